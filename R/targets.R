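# miRNA target prediction by positional complementarity rules.
#
# A duplex aligns the miRNA (5'->3') antiparallel to a transcript site
# (5'->3'): miRNA position i (numbered 1..L from the miRNA 5' end) pairs
# with site position L-i+1. Watson-Crick pairs are matches, G:U/U:G are
# wobbles weighted 0.5 mismatch in sum rules, everything else is a full
# mismatch weighted 1.

# Per-position duplex status for miRNA vs site, both 5'->3'.
# Returns character vector over {"match", "GU", "mismatch"}, indexed by
# miRNA position.
.duplex_status <- function(mirna, site) {
  m <- strsplit(.as_dna(mirna), "")[[1]]
  s <- rev(strsplit(.as_dna(site), "")[[1]])  # s[i] faces miRNA position i
  wc <- (m == "A" & s == "T") | (m == "T" & s == "A") |
        (m == "G" & s == "C") | (m == "C" & s == "G")
  gu <- (m == "G" & s == "T") | (m == "T" & s == "G")
  status <- rep("mismatch", length(m))
  status[gu] <- "GU"
  status[wc] <- "match"
  status
}

#' Score a miRNA/target-site duplex
#'
#' @param mirna miRNA sequence, 5' to 3'.
#' @param site transcript site sequence, 5' to 3' on the transcript, same
#'   length as the miRNA (ungapped duplex).
#' @return object of class `duplex_score`: list with `status` (per-miRNA-
#'   position vector of match/GU/mismatch), `total_mismatches` (GU = 0.5),
#'   `max_adjacent_mismatches` (longest run of full mismatches),
#'   `adjacent_2_12` (number of adjacent full-mismatch pairs within miRNA
#'   positions 2-12), `mismatches_10_11` (full mismatches at positions
#'   10-11), and `mismatches_1_12` (weighted mismatches in positions 1-12).
#' @export
score_duplex <- function(mirna, site) {
  stopifnot(is.character(mirna), is.character(site),
            length(mirna) == 1, length(site) == 1)
  if (nchar(mirna) != nchar(site)) {
    stop("miRNA and site must have equal length (ungapped duplex)",
         call. = FALSE)
  }
  .check_nt(c(mirna, site))
  status <- .duplex_status(mirna, site)
  w <- ifelse(status == "mismatch", 1, ifelse(status == "GU", 0.5, 0))
  mm <- status == "mismatch"
  runs <- rle(mm)
  max_run <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  idx12 <- seq_len(min(12L, length(status)))
  adj_2_12 <- 0L
  hi <- min(11L, length(status) - 1L)
  if (hi >= 2L) {
    adj_2_12 <- sum(mm[2:hi] & mm[3:(hi + 1L)])
  }
  structure(list(
    status = status,
    total_mismatches = sum(w),
    max_adjacent_mismatches = as.integer(max_run),
    adjacent_2_12 = as.integer(adj_2_12),
    mismatches_10_11 = as.integer(sum(mm[intersect(10:11, seq_along(mm))])),
    mismatches_1_12 = sum(w[idx12])
  ), class = "duplex_score")
}

# Vectorised rule kernel over a status weight matrix (rows = duplexes,
# columns = miRNA positions; entries 0 = match, 0.5 = GU, 1 = mismatch).
# Returns a logical vector: does each row pass all five rules?
# Rules: (1) total weighted mismatches <= 4; (2) longest run of full
# mismatches <= 2; (3) no two adjacent full mismatches within positions
# 2-12; (4) no full mismatch at positions 10-11; (5) weighted mismatches
# in positions 1-12 <= 2.5.
rule_kernel <- function(w) {
  stopifnot(is.matrix(w))
  L <- ncol(w)
  mm <- w == 1
  r1 <- rowSums(w) <= 4
  run3 <- rep(FALSE, nrow(w))
  if (L >= 3) {
    for (i in seq_len(L - 2)) {
      run3 <- run3 | (mm[, i] & mm[, i + 1] & mm[, i + 2])
    }
  }
  r2 <- !run3
  adj <- rep(FALSE, nrow(w))
  hi <- min(11L, L - 1L)
  if (hi >= 2L) {
    for (i in 2:hi) adj <- adj | (mm[, i] & mm[, i + 1])
  }
  r3 <- !adj
  r4 <- if (L >= 10) {
    cols <- intersect(10:11, seq_len(L))
    rowSums(mm[, cols, drop = FALSE]) == 0
  } else rep(TRUE, nrow(w))
  r5 <- rowSums(w[, seq_len(min(12L, L)), drop = FALSE]) <= 2.5
  r1 & r2 & r3 & r4 & r5
}

#' Do the five complementarity rules accept a duplex?
#'
#' The rules, with G:U wobbles counting 0.5 mismatches in the sum rules
#' and positions numbered from the miRNA 5' end:
#' no more than 4 total mismatches; no more than 2 adjacent full
#' mismatches; no adjacent full mismatches within positions 2-12; no full
#' mismatches at positions 10-11; no more than 2.5 mismatches within
#' positions 1-12. Wobbles neither form nor break adjacency (they are
#' weighted only in the sum rules).
#'
#' @param d a `duplex_score` from [score_duplex()].
#' @return logical scalar.
#' @export
passes_rules <- function(d) {
  stopifnot(inherits(d, "duplex_score"))
  w <- ifelse(d$status == "mismatch", 1, ifelse(d$status == "GU", 0.5, 0))
  as.logical(rule_kernel(matrix(w, nrow = 1)))
}

#' Find miRNA target sites on transcripts
#'
#' Slides each miRNA over every transcript window of its length, scores
#' the ungapped duplex, and reports windows accepted by the five rules.
#' A cheap vectorised total-mismatch prefilter is applied first; windows
#' at or under the total threshold are then fully scored by
#' [score_duplex()]/[passes_rules()].
#'
#' @param mirnas named character vector of mature miRNA sequences.
#' @param transcripts named character vector (or `DNAStringSet`) of
#'   transcript sequences. Transcripts shorter than a miRNA are skipped.
#' @return list with `sites` (data.frame: `mirna`, `transcript`, `start`,
#'   `total_mismatches`; `start` is the 1-based transcript position of the
#'   site's 5'-most base), `target_counts` (per-miRNA distinct target-gene
#'   counts, named integer), and `histogram` (counts of miRNAs per
#'   target-number bin: 1, 2-3, 4-10, 11-30, 31-100, >100).
#' @export
find_targets <- function(mirnas, transcripts) {
  stopifnot(!is.null(names(mirnas)), !is.null(names(transcripts)))
  if (methods::is(transcripts, "DNAStringSet")) {
    transcripts <- setNames(as.character(transcripts), names(transcripts))
  }
  sites <- list()
  t_codes <- lapply(transcripts, function(x) strsplit(.as_dna(x), "")[[1]])
  for (mi in names(mirnas)) {
    mseq <- .as_dna(mirnas[[mi]])
    m <- strsplit(mseq, "")[[1]]
    L <- length(m)
    for (tx in names(transcripts)) {
      tc <- t_codes[[tx]]
      n_win <- length(tc) - L + 1L
      if (n_win < 1L) next
      # weight of miRNA position i against site base tc[start + L - i]
      tot <- numeric(n_win)
      for (i in seq_len(L)) {
        b <- tc[seq.int(L - i + 1L, length.out = n_win)]
        mi_b <- m[i]
        wc <- (mi_b == "A" & b == "T") | (mi_b == "T" & b == "A") |
              (mi_b == "G" & b == "C") | (mi_b == "C" & b == "G")
        gu <- (mi_b == "G" & b == "T") | (mi_b == "T" & b == "G")
        tot <- tot + ifelse(wc, 0, ifelse(gu, 0.5, 1))
      }
      for (s in which(tot <= 4)) {
        site <- substr(transcripts[[tx]], s, s + L - 1L)
        d <- score_duplex(mirnas[[mi]], site)
        if (passes_rules(d)) {
          sites[[length(sites) + 1L]] <- data.frame(
            mirna = mi, transcript = tx, start = s,
            total_mismatches = d$total_mismatches,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  sites <- if (length(sites)) do.call(rbind, sites) else
    data.frame(mirna = character(0), transcript = character(0),
               start = integer(0), total_mismatches = numeric(0),
               stringsAsFactors = FALSE)
  counts <- vapply(split(sites$transcript, sites$mirna),
                   function(x) length(unique(x)), integer(1))
  breaks <- c(0, 1, 3, 10, 30, 100, Inf)
  labels <- c("1", "2-3", "4-10", "11-30", "31-100", ">100")
  histogram <- table(cut(counts, breaks = breaks, labels = labels))
  list(sites = sites, target_counts = counts,
       histogram = as.data.frame(histogram, responseName = "n_mirnas"))
}

#' Annotation-term enrichment factors for a target gene set
#'
#' For each term, the enrichment factor is `(k/n) / (K/N)`: the share of
#' target genes carrying the term over its share in the gene universe.
#' Significance is the hypergeometric upper-tail probability of drawing at
#' least `k` term-carrying genes in `n` draws from the universe, BH
#' adjusted by default.
#'
#' @param targets character vector of target gene ids (deduplicated).
#' @param annotation data.frame with columns `gene`, `term`.
#' @param universe character vector of all genes (must contain `targets`).
#' @param adjust apply Benjamini-Hochberg adjustment (default TRUE).
#' @return data.frame with columns `term`, `k`, `n`, `K`, `N`,
#'   `enrichment_factor`, `pvalue` (and `padj` when `adjust`).
#' @export
enrichment <- function(targets, annotation, universe, adjust = TRUE) {
  stopifnot(all(c("gene", "term") %in% names(annotation)))
  targets <- unique(targets)
  universe <- unique(universe)
  if (!all(targets %in% universe)) {
    stop("all target genes must be in the universe", call. = FALSE)
  }
  if (!all(annotation$gene %in% universe)) {
    stop("annotation references genes absent from the universe",
         call. = FALSE)
  }
  ann <- annotation[!duplicated(annotation[c("gene", "term")]), ]
  n <- length(targets)
  N <- length(universe)
  terms <- unique(ann$term)
  res <- lapply(terms, function(tm) {
    genes <- ann$gene[ann$term == tm]
    K <- length(genes)
    k <- sum(targets %in% genes)
    data.frame(term = tm, k = k, n = n, K = K, N = N,
               enrichment_factor = (k / n) / (K / N),
               pvalue = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (adjust) res$padj <- p.adjust(res$pvalue, method = "BH")
  res[order(res$pvalue, -res$enrichment_factor), , drop = FALSE]
}
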