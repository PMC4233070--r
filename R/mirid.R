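# Conserved miRNA identification by exact reference matching, and novel
# miRNA prediction by genomic window excision, folding and hairpin
# criteria.

#' miRNA family from a miRBase-style name
#'
#' Strips species prefixes ("xxx-"), mature-arm suffixes ("-5p"/"-3p"),
#' star marks ("*") and trailing variant letters/numbers after the family
#' number, e.g. "pbr-miR156k" -> "miR156", "miR4414a*" -> "miR4414".
#'
#' @param name character vector of miRNA names.
#' @return character vector of family names.
#' @export
mirna_family <- function(name) {
  x <- sub("^[a-z]{2,4}-", "", name)
  x <- sub("-(5p|3p)$", "", x)
  x <- sub("\\*$", "", x)
  sub("^((mi|MIR|miR)[A-Za-z]*[0-9]+).*$", "\\1", x)
}

#' Match clean reads to a known mature miRNA reference
#'
#' A clean sequence counts toward a known miRNA iff it is identical to
#' the reference mature sequence (T/U equivalent). Counts are read
#' counts; families are derived from reference names.
#'
#' @param clean a `clean_read_set` or a list of them (counts summed into
#'   a per-library matrix).
#' @param reference named character vector (or `DNAStringSet`) of mature
#'   miRNA sequences; names must be unique.
#' @return list with `counts` (matrix miRNA x library of read counts,
#'   only matched miRNAs), `matched` (data.frame: `name`, `family`,
#'   `sequence`, `total`), and `unmatched` (per-library list of records
#'   data.frames that did not match any reference entry).
#' @export
match_known <- function(clean, reference) {
  if (inherits(clean, "clean_read_set")) clean <- list(clean)
  ref_seq <- .as_dna(as.character(reference))
  ref_names <- names(reference)
  if (is.null(ref_names) || anyDuplicated(ref_names)) {
    stop("reference names must be present and unique", call. = FALSE)
  }
  if (length(ref_seq) == 0) stop("reference is empty", call. = FALSE)
  lut <- setNames(ref_names, ref_seq)  # sequence -> name (first wins)
  lib_ids <- vapply(clean, function(x) as.character(x$library_id),
                    character(1))
  counts <- matrix(0L, nrow = length(ref_names), ncol = length(clean),
                   dimnames = list(ref_names, lib_ids))
  unmatched <- list()
  for (i in seq_along(clean)) {
    rec <- clean[[i]]$records
    hit <- lut[rec$sequence]
    matched_sel <- !is.na(hit)
    if (any(matched_sel)) {
      agg <- rowsum(rec$count[matched_sel], hit[matched_sel])
      counts[rownames(agg), i] <- counts[rownames(agg), i] + agg[, 1]
    }
    unmatched[[lib_ids[i]]] <- rec[!matched_sel, , drop = FALSE]
  }
  total <- rowSums(counts)
  keep <- total > 0
  matched <- data.frame(name = ref_names[keep],
                        family = mirna_family(ref_names[keep]),
                        sequence = ref_seq[keep],
                        total = total[keep], stringsAsFactors = FALSE)
  list(counts = counts[keep, , drop = FALSE], matched = matched,
       unmatched = unmatched)
}

#' Excise genomic precursor-candidate windows around mapped reads
#'
#' For each mapped read locus, two windows are excised on the read's
#' strand: one extending `flank` nt upstream of the read and one
#' extending `flank` nt downstream (each capped at `max_len` total).
#' Windows are clipped at chromosome bounds and flagged when clipped.
#'
#' @param genome named `DNAStringSet` or character vector.
#' @param loci data.frame with columns `chrom`, `start`, `end`, `strand`
#'   (1-based inclusive read loci), plus optionally `sequence`/`count`.
#' @param flank flank length in nt (default 150).
#' @param max_len maximum window length (default 374).
#' @return data.frame with columns of `loci` plus `win_start`, `win_end`,
#'   `window` (genomic sequence, reverse-complemented on minus strand so
#'   it reads 5'->3' with the mature on it), `mature_offset` (0-based
#'   offset of the read within the window), and `clipped`.
#' @export
excise_candidates <- function(genome, loci, flank = 150L, max_len = 374L) {
  genome <- .as_genome(genome)
  chrom_len <- setNames(BiocGenerics::width(genome), names(genome))
  out <- list()
  for (r in seq_len(nrow(loci))) {
    chrom <- loci$chrom[r]
    s <- loci$start[r]; e <- loci$end[r]
    read_len <- e - s + 1L
    fl <- min(flank, max_len - read_len)
    for (side in c("up", "down")) {
      if (side == "up") { ws <- s - fl; we <- e } else { ws <- s; we <- e + fl }
      clipped <- ws < 1L || we > chrom_len[[chrom]]
      ws_c <- max(1L, ws); we_c <- min(chrom_len[[chrom]], we)
      win <- as.character(Biostrings::subseq(genome[[chrom]], ws_c, we_c))
      if (loci$strand[r] == "-") {
        win <- revcomp(win)
        mat_off <- we_c - e
      } else {
        mat_off <- s - ws_c
      }
      row <- loci[r, , drop = FALSE]
      row$win_start <- ws_c; row$win_end <- we_c
      row$window <- win
      row$mature_offset <- as.integer(mat_off)
      row$side <- side
      row$clipped <- clipped
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Locate the star arm paired to the mature region in a pair table: the
# largest contiguous cluster of mature partners outside the mature
# itself (stray long-range pairs into flanking sequence are ignored).
# Returns NULL when fewer than `min_pairs` mature positions support it.
.star_span <- function(pt, m_start, m_end, min_pairs = 4L,
                       max_gap = 10L) {
  mpos <- m_start:m_end
  partners <- pt[mpos]
  sel <- !is.na(partners) & (partners < m_start | partners > m_end)
  mpos <- mpos[sel]
  partners <- partners[sel]
  if (length(partners) < min_pairs) return(NULL)
  ord <- order(partners)
  partners <- partners[ord]; mpos <- mpos[ord]
  cl <- cumsum(c(1L, as.integer(diff(partners) > max_gap)))
  sizes <- tabulate(cl)
  best <- which.max(sizes)
  if (sizes[best] < min_pairs) return(NULL)
  keep <- cl == best
  list(span = c(min(partners[keep]), max(partners[keep])),
       m_lo = min(mpos[keep]), m_hi = max(mpos[keep]))
}

#' Evaluate hairpin criteria on a precursor candidate
#'
#' The candidate window is folded, the star arm is located from the base
#' pairs of the mature region, the candidate is trimmed to the
#' mature..star span and refolded, and the community (Meyers-style)
#' criteria are evaluated on the trimmed precursor: precursor length in
#' [64, 374]; a single mature/star junction (every terminal loop lies
#' between the two arms; micro-stems within the junction loop are
#' tolerated); mature length in [18, 25]; at least 16 mature nucleotides paired
#' to the star arm; at most 4 unpaired (mismatched) mature positions in
#' the duplex; no asymmetric bulge larger than 2 nt within the duplex;
#' folding energy at or below `mfe_max`.
#'
#' @param window candidate window sequence (5'->3', mature on this strand).
#' @param mature_offset 0-based offset of the mature read in the window.
#' @param mature_length mature read length in nt.
#' @param mfe_max MFE acceptance threshold in kcal/mol (default -18).
#' @param backend folding backend passed to [fold_rna()].
#' @return list with `accept`, `flags` (named logicals:
#'   `hairpin_single_loop`, `mature_pairing_ok`, `duplex_mismatches_ok`,
#'   `bulge_ok`, `mfe_ok`, `length_ok`), `precursor` (trimmed sequence),
#'   `structure`, `mfe`, `mature_arm` ("5p"/"3p"), `mature_offset` and
#'   `star_offset` (0-based, in the trimmed precursor; NA when no star).
#' @export
evaluate_hairpin <- function(window, mature_offset, mature_length,
                             mfe_max = -18, backend = NULL) {
  flags <- c(hairpin_single_loop = FALSE, mature_pairing_ok = FALSE,
             duplex_mismatches_ok = FALSE, bulge_ok = FALSE,
             mfe_ok = FALSE, length_ok = FALSE)
  fail <- function(extra = list()) {
    c(list(accept = FALSE, flags = flags), extra)
  }
  m_start <- mature_offset + 1L
  m_end <- mature_offset + mature_length
  if (m_end > nchar(window) || m_start < 1L) {
    stop("mature region outside window", call. = FALSE)
  }
  fold0 <- fold_rna(window, backend = backend)
  pt0 <- pair_table(fold0$structure)
  ss <- .star_span(pt0, m_start, m_end)
  if (is.null(ss)) {
    return(fail(list(precursor = window, structure = fold0$structure,
                     mfe = fold0$mfe, mature_arm = NA_character_,
                     mature_offset = NA_integer_,
                     star_offset = NA_integer_)))
  }
  # trim to the mature..star span and refold; the star-side bound is
  # padded so mature edge positions whose pairs went astray in the
  # window fold still find their true star complement after the refold
  if (ss$span[1] > m_end) {
    p_start <- m_start
    p_end <- min(nchar(window), ss$span[2] + (ss$m_lo - m_start) + 2L)
  } else {
    p_end <- m_end
    p_start <- max(1L, ss$span[1] - (m_end - ss$m_hi) - 2L)
  }
  precursor <- substr(window, p_start, p_end)
  fold1 <- fold_rna(precursor, backend = backend)
  pt <- pair_table(fold1$structure)
  mm_start <- m_start - p_start + 1L
  mm_end <- m_end - p_start + 1L
  ss1 <- .star_span(pt, mm_start, mm_end)
  span1 <- if (is.null(ss1)) NULL else ss1$span

  flags["length_ok"] <- nchar(precursor) >= 64 && nchar(precursor) <= 374 &&
    mature_length >= 18 && mature_length <= 25
  flags["mfe_ok"] <- fold1$mfe <= mfe_max

  mature_arm <- if (mm_start <= (nchar(precursor) - mm_end + 1L)) "5p" else "3p"
  star_offset <- NA_integer_
  if (!is.null(span1)) {
    star_offset <- span1[1] - 1L
    # pairing of the mature to the star region
    partners <- pt[mm_start:mm_end]
    to_star <- !is.na(partners) & (partners >= span1[1]) &
      (partners <= span1[2]) & (partners < mm_start | partners > mm_end)
    n_paired <- sum(to_star)
    flags["mature_pairing_ok"] <- n_paired >= 16
    flags["duplex_mismatches_ok"] <- (mature_length - n_paired) <= 4

    # asymmetric bulges within the duplex: compare gaps between
    # consecutive star-paired mature positions on both arms
    idx <- which(to_star)
    bulge_ok <- TRUE
    if (length(idx) >= 2) {
      mpos <- (mm_start:mm_end)[idx]
      spos <- partners[idx]
      gaps_m <- diff(mpos) - 1L
      gaps_s <- abs(diff(spos)) - 1L
      bulge_ok <- all(abs(gaps_m - gaps_s) <= 2L)
    }
    flags["bulge_ok"] <- bulge_ok

    # a single mature/star junction: every terminal loop of the trimmed
    # precursor lies between the two arms (micro-stems inside the
    # junction are tolerated; loops inside either arm are not)
    loops <- terminal_loops(fold1$structure)
    lo <- min(mm_end, span1[2]); hi <- max(mm_start, span1[1])
    between <- loops$start > lo - 1L & loops$end < hi + 1L
    flags["hairpin_single_loop"] <- nrow(loops) >= 1 && all(between)
  }
  list(accept = all(flags), flags = flags, precursor = precursor,
       structure = fold1$structure, mfe = fold1$mfe,
       mature_arm = mature_arm,
       mature_offset = mm_start - 1L, star_offset = star_offset)
}

#' Predict novel miRNAs from unannotated reads
#'
#' Unmatched/unannotated unique sequences with a summed read count of at
#' least `min_count` over all libraries and a mature-compatible length
#' are mapped exactly to the genome; around every locus, upstream and
#' downstream windows are excised, folded and evaluated by
#' [evaluate_hairpin()]. Accepted candidates are deduplicated by mature
#' sequence.
#'
#' @param records list (per library) of data.frames with `sequence` and
#'   `count` — typically the `unmatched` element of [match_known()],
#'   optionally restricted to the unannotated category.
#' @param genome named `DNAStringSet` or character vector.
#' @param min_count minimum summed read count (default 3).
#' @param min_len,max_len mature length window (defaults 18 and 25 nt).
#' @param flank excision flank (default 150 nt).
#' @param mfe_max hairpin MFE threshold (default -18 kcal/mol).
#' @param max_loci skip sequences with more genomic loci than this
#'   (repeat-derived; default 20).
#' @param exclude sequences that must never be called novel (typically
#'   the known mature reference; T/U equivalent), or NULL.
#' @return list with `novel` (data.frame: `name`, `sequence`, `chrom`,
#'   `start`, `end`, `strand`, `mature_arm`, `precursor`, `structure`,
#'   `mfe`, per-library counts as attribute), `counts` (matrix novel x
#'   library), and `candidates` (all evaluated windows with flags).
#' @export
predict_novel <- function(records, genome, min_count = 3L, min_len = 18L,
                          max_len = 25L, flank = 150L, mfe_max = -18,
                          max_loci = 20L, exclude = NULL) {
  stopifnot(is.list(records), length(records) > 0)
  lib_ids <- names(records)
  if (is.null(lib_ids)) lib_ids <- sprintf("lib%d", seq_along(records))
  all_seq <- unlist(lapply(records, function(r) r$sequence))
  all_cnt <- unlist(lapply(records, function(r) r$count))
  if (length(all_seq) == 0) {
    return(list(novel = .empty_novel(), counts = NULL, candidates = NULL))
  }
  tot <- rowsum(all_cnt, all_seq)
  seqs <- rownames(tot)
  keep <- tot[, 1] >= min_count & nchar(seqs) >= min_len &
    nchar(seqs) <= max_len
  if (!is.null(exclude)) {
    keep <- keep & !(seqs %in% .as_dna(as.character(exclude)))
  }
  seqs <- seqs[keep]
  if (length(seqs) == 0) {
    return(list(novel = .empty_novel(), counts = NULL, candidates = NULL))
  }
  hits <- .map_many(genome, seqs)
  cands <- list()
  accepted <- list()
  for (i in seq_along(seqs)) {
    h <- hits[hits$seq_index == i, , drop = FALSE]
    if (nrow(h) == 0 || nrow(h) > max_loci) next
    loci <- data.frame(chrom = h$chrom, start = h$start, end = h$end,
                       strand = h$strand, stringsAsFactors = FALSE)
    wins <- excise_candidates(genome, loci, flank = flank)
    best <- NULL
    for (w in seq_len(nrow(wins))) {
      ev <- evaluate_hairpin(wins$window[w], wins$mature_offset[w],
                             nchar(seqs[i]), mfe_max = mfe_max)
      cands[[length(cands) + 1L]] <- data.frame(
        sequence = seqs[i], chrom = wins$chrom[w],
        win_start = wins$win_start[w], win_end = wins$win_end[w],
        strand = wins$strand[w], side = wins$side[w],
        mfe = ev$mfe, accept = ev$accept,
        t(as.data.frame(ev$flags)), stringsAsFactors = FALSE)
      if (ev$accept && (is.null(best) || ev$mfe < best$ev$mfe)) {
        best <- list(ev = ev, w = w)
      }
    }
    if (!is.null(best)) {
      ev <- best$ev; w <- best$w
      accepted[[length(accepted) + 1L]] <- data.frame(
        sequence = seqs[i], chrom = wins$chrom[w],
        start = wins$start[w], end = wins$end[w],
        strand = wins$strand[w], mature_arm = ev$mature_arm,
        precursor = ev$precursor, structure = ev$structure, mfe = ev$mfe,
        stringsAsFactors = FALSE)
    }
  }
  candidates <- if (length(cands)) do.call(rbind, cands) else NULL
  if (length(accepted) == 0) {
    return(list(novel = .empty_novel(), counts = NULL,
                candidates = candidates))
  }
  novel <- do.call(rbind, accepted)
  novel <- novel[!duplicated(novel$sequence), , drop = FALSE]
  novel <- cbind(name = sprintf("novel-mir-%03d", seq_len(nrow(novel))),
                 novel, stringsAsFactors = FALSE)
  rownames(novel) <- NULL
  counts <- vapply(records, function(r) {
    idx <- match(novel$sequence, r$sequence)
    ifelse(is.na(idx), 0L, r$count[idx])
  }, integer(nrow(novel)))
  counts <- matrix(counts, nrow = nrow(novel),
                   dimnames = list(novel$name, lib_ids))
  list(novel = novel, counts = counts, candidates = candidates)
}

.empty_novel <- function() {
  data.frame(name = character(0), sequence = character(0),
             chrom = character(0), start = integer(0), end = integer(0),
             strand = character(0), mature_arm = character(0),
             precursor = character(0), structure = character(0),
             mfe = numeric(0), stringsAsFactors = FALSE)
}
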