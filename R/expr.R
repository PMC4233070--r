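# Differential expression of miRNAs across developmental stages, on
# digital read counts: TPM normalisation, pairwise zero/low-expression
# handling against the control stage, log2 fold change, and the
# conditional digital-count significance test.

#' TPM-normalise a count matrix
#'
#' `tpm = count * 1e6 / library_total`, with the library total being the
#' clean-read count of the library (not the sum of the matrix rows). No
#' pseudocounts are applied at this step.
#'
#' @param counts numeric matrix, miRNAs x stages.
#' @param totals numeric vector of clean-read totals per stage (all > 0),
#'   recycled across rows; names (if any) must match `colnames(counts)`.
#' @return numeric matrix of TPM values with the same dimnames.
#' @export
tpm_normalize <- function(counts, totals) {
  counts <- as.matrix(counts)
  if (any(totals <= 0)) stop("library totals must be > 0", call. = FALSE)
  if (length(totals) != ncol(counts)) {
    stop("one total per library column required", call. = FALSE)
  }
  if (!is.null(names(totals)) && !is.null(colnames(counts)) &&
      !identical(names(totals), colnames(counts))) {
    totals <- totals[colnames(counts)]
  }
  sweep(counts, 2, totals, function(x, t) x * 1e6 / t)
}

#' Pairwise zero/low-expression adjustment for a control/treatment pair
#'
#' A TPM of zero on either side is revised to 0.01; the pair is flagged
#' excluded when both adjusted values are below 1 (too low to compare).
#'
#' @param control,treat TPM values (same miRNA, two stages).
#' @return list with `control`, `treat` (adjusted values) and `excluded`.
#' @export
adjust_for_de <- function(control, treat) {
  stopifnot(is.numeric(control), is.numeric(treat),
            control >= 0, treat >= 0)
  if (control == 0) control <- 0.01
  if (treat == 0) treat <- 0.01
  list(control = control, treat = treat,
       excluded = control < 1 && treat < 1)
}

#' Log2 fold change of treatment over control
#'
#' @param treat,control adjusted TPM values (> 0).
#' @return log2(treat / control).
#' @export
fold_change <- function(treat, control) {
  stopifnot(treat > 0, control > 0)
  log2(treat / control)
}

#' Digital-count significance test for two library counts
#'
#' Exact conditional test for whether a read count `y` in a library of
#' `N2` total reads is compatible with count `x` in a library of `N1`
#' reads, under the digital (Poisson-sampled) expression model — the
#' conditioned, symmetric form of the classical Audic-Claverie
#' comparison. Conditional on the total `x + y`, `y` follows a binomial
#' with size `x + y` and success probability `N2 / (N1 + N2)`; the
#' p-value is two-sided by doubling the smaller tail (both tails include
#' the observation) and capping at 1. The conditioning makes the test
#' exactly symmetric: `de_test(x, y, n1, n2) == de_test(y, x, n2, n1)`.
#'
#' @param x control count (non-negative integer).
#' @param y treatment count (non-negative integer).
#' @param n1 control library total (> 0).
#' @param n2 treatment library total (> 0).
#' @return p-value in (0, 1].
#' @export
de_test <- function(x, y, n1, n2) {
  stopifnot(x >= 0, y >= 0, x == round(x), y == round(y), n1 > 0, n2 > 0)
  n <- x + y
  if (n == 0) return(1)
  p2 <- n2 / (n1 + n2)
  lower <- stats::pbinom(y, n, p2)
  upper <- stats::pbinom(y - 1, n, p2, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

#' Significance label at the 0.05 / 0.01 thresholds
#'
#' @param p p-value.
#' @return one of "none", "p05" (p < 0.05) or "p01" (p < 0.01).
#' @export
significance_label <- function(p) {
  ifelse(p < 0.01, "p01", ifelse(p < 0.05, "p05", "none"))
}

#' Classify an expression trend across ordered stages
#'
#' `increasing`: non-strictly monotone up with at least one strict step
#' (so the final stage exceeds the first); `decreasing` is symmetric;
#' anything else (including a peak followed by decline) is `other`.
#'
#' @param tpm numeric vector of per-stage (adjusted) TPM values in stage
#'   order, length >= 3.
#' @return one of "increasing", "decreasing", "other".
#' @export
classify_trend <- function(tpm) {
  stopifnot(is.numeric(tpm), length(tpm) >= 3)
  d <- diff(tpm)
  if (all(d >= 0) && any(d > 0)) return("increasing")
  if (all(d <= 0) && any(d < 0)) return("decreasing")
  "other"
}

#' Differential expression table against a control stage
#'
#' Runs the full per-stage comparison: TPM, pairwise zero/low adjustment,
#' log2 fold change and the digital-count test of every non-control stage
#' against the control, plus a per-miRNA trend over adjusted TPM.
#'
#' @param counts integer matrix, miRNAs x stages (raw clean-read counts).
#' @param totals per-stage clean-read totals.
#' @param control control stage column name (default "15DAF").
#' @param adjust_p apply Benjamini-Hochberg adjustment per comparison
#'   (off by default; the raw thresholds are the reporting convention).
#' @return list with `records` (long data.frame: `mirna`, `stage`,
#'   `raw_count`, `tpm`, `tpm_adjusted`, `log2fc`, `pvalue`,
#'   `significance`, `excluded`) and `trend` (named vector per miRNA).
#' @export
de_table <- function(counts, totals, control = "15DAF", adjust_p = FALSE) {
  counts <- as.matrix(counts)
  stopifnot(control %in% colnames(counts))
  tpm <- tpm_normalize(counts, totals)
  stages <- colnames(counts)
  treat_stages <- setdiff(stages, control)
  recs <- list()
  adj_tpm <- tpm  # per-miRNA adjusted values (zeros revised pairwise)
  for (mi in rownames(counts)) {
    for (st in treat_stages) {
      pair <- adjust_for_de(tpm[mi, control], tpm[mi, st])
      adj_tpm[mi, st] <- pair$treat
      adj_tpm[mi, control] <- pair$control
      if (pair$excluded) {
        recs[[length(recs) + 1L]] <- data.frame(
          mirna = mi, stage = st, raw_count = counts[mi, st],
          tpm = tpm[mi, st], tpm_adjusted = pair$treat,
          log2fc = NA_real_, pvalue = NA_real_, significance = "none",
          excluded = TRUE, stringsAsFactors = FALSE)
        next
      }
      p <- de_test(counts[mi, control], counts[mi, st],
                   totals[[control]], totals[[st]])
      recs[[length(recs) + 1L]] <- data.frame(
        mirna = mi, stage = st, raw_count = counts[mi, st],
        tpm = tpm[mi, st], tpm_adjusted = pair$treat,
        log2fc = fold_change(pair$treat, pair$control),
        pvalue = p, significance = significance_label(p),
        excluded = FALSE, stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, recs)
  if (adjust_p) {
    for (st in treat_stages) {
      sel <- records$stage == st & !records$excluded
      records$padj[sel] <- p.adjust(records$pvalue[sel], method = "BH")
      records$significance[sel] <- significance_label(records$padj[sel])
    }
  }
  trend <- vapply(rownames(counts),
                  function(mi) classify_trend(adj_tpm[mi, stages]),
                  character(1))
  list(records = records, trend = trend)
}

#' Comparative ddCt relative expression from a qPCR Ct table
#'
#' `dCt = ct_target - ct_reference` per (miRNA, stage); `ddCt` is taken
#' relative to the control stage and relative expression is `2^(-ddCt)`,
#' so the control stage is 1 by construction.
#'
#' @param ct data.frame with columns `mirna`, `stage`, `gene`, `ct`; the
#'   reference gene must have a Ct for every (mirna, stage) combination
#'   present for the target.
#' @param reference reference (internal control) gene name, e.g. "5S".
#' @param control control stage label.
#' @return data.frame with columns `mirna`, `stage`, `ct_target`,
#'   `ct_reference`, `relative_expression`.
#' @export
ddct <- function(ct, reference, control) {
  stopifnot(all(c("mirna", "stage", "gene", "ct") %in% names(ct)))
  ref <- ct[ct$gene == reference, ]
  tgt <- ct[ct$gene != reference, ]
  if (nrow(ref) == 0) stop("reference gene not found: ", reference,
                           call. = FALSE)
  out <- lapply(unique(tgt$mirna), function(mi) {
    sub <- tgt[tgt$mirna == mi, ]
    ref_ct <- setNames(ref$ct, ref$stage)
    missing_ref <- setdiff(sub$stage, names(ref_ct))
    if (length(missing_ref) > 0) {
      stop(sprintf("missing reference Ct for stage(s): %s",
                   paste(missing_ref, collapse = ", ")), call. = FALSE)
    }
    if (!control %in% sub$stage) {
      stop("control stage absent for miRNA ", mi, call. = FALSE)
    }
    dct <- sub$ct - ref_ct[sub$stage]
    dct_control <- dct[sub$stage == control][1]
    data.frame(mirna = mi, stage = sub$stage, ct_target = sub$ct,
               ct_reference = as.numeric(ref_ct[sub$stage]),
               relative_expression = 2^(-(dct - dct_control)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
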