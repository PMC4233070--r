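#' Map a mature miRNA sequence to a genome by exact matching
#'
#' Reports every exact occurrence of the sequence on the forward strand and
#' every occurrence of its reverse complement as a minus-strand locus.
#' Overlapping occurrences are all reported; the number of rows is the
#' transcript-site count of the sequence. Coordinates are 1-based inclusive.
#'
#' @param genome named `DNAStringSet` (or named character vector) of
#'   chromosome sequences.
#' @param sequence nucleotide string, length >= 18 (T/U equivalent).
#' @return data.frame with columns `chrom`, `start`, `end`, `strand`.
#' @export
map_mature <- function(genome, sequence) {
  genome <- .as_genome(genome)
  stopifnot(is.character(sequence), length(sequence) == 1)
  if (nchar(sequence) < 18) stop("sequence must be >= 18 nt", call. = FALSE)
  .check_nt(sequence)
  fwd <- Biostrings::DNAString(.as_dna(sequence))
  rev <- Biostrings::reverseComplement(fwd)
  out <- list()
  for (chrom in names(genome)) {
    subj <- genome[[chrom]]
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") fwd else rev
      hits <- Biostrings::matchPattern(pat, subj)
      if (length(hits) > 0) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom,
          start = BiocGenerics::start(hits),
          end = BiocGenerics::end(hits),
          strand = strand,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start, res$strand), , drop = FALSE]
}

#' Map a set of mature miRNA sequences to a genome
#'
#' Convenience wrapper around [map_mature()] for a named set of sequences.
#'
#' @param genome named `DNAStringSet` or character vector of chromosomes.
#' @param sequences named character vector of mature sequences.
#' @return data.frame with columns `name`, `chrom`, `start`, `end`,
#'   `strand`; one row per genomic occurrence.
#' @export
map_mature_set <- function(genome, sequences) {
  stopifnot(!is.null(names(sequences)), !anyDuplicated(names(sequences)))
  out <- lapply(names(sequences), function(nm) {
    loci <- map_mature(genome, sequences[[nm]])
    if (nrow(loci) > 0) cbind(name = nm, loci, stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) {
    return(data.frame(name = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Detect genomic miRNA clusters by distance chaining
#'
#' Single-linkage chaining per chromosome, strand-agnostic: loci are sorted
#' by start and chained while the gap between consecutive loci
#' (`next start - current end`) is at most `d`. Chains with at least two
#' distinct miRNA loci are reported as clusters.
#'
#' @param loci data.frame with columns `name`, `chrom`, `start`, `end`
#'   (strand ignored), e.g. from [map_mature_set()].
#' @param d maximum inter-locus gap in nucleotides (> 0).
#' @return object of class `cluster_set`: list with `d` and `clusters`, a
#'   list of data.frames (cluster members sorted by start).
#' @export
detect_clusters <- function(loci, d) {
  stopifnot(is.numeric(d), length(d) == 1, d > 0)
  req <- c("name", "chrom", "start", "end")
  stopifnot(all(req %in% names(loci)))
  clusters <- list()
  for (chrom in unique(loci$chrom)) {
    sub <- loci[loci$chrom == chrom, , drop = FALSE]
    sub <- sub[order(sub$start, sub$end), , drop = FALSE]
    if (nrow(sub) == 0) next
    chain_id <- cumsum(c(1L, as.integer(
      sub$start[-1] - cummax_end(sub$end)[-nrow(sub)] > d)))
    for (id in unique(chain_id)) {
      members <- sub[chain_id == id, , drop = FALSE]
      rownames(members) <- NULL
      if (nrow(members) >= 2) clusters[[length(clusters) + 1L]] <- members
    }
  }
  structure(list(d = d, clusters = clusters), class = "cluster_set")
}

# Running maximum of interval ends, so chaining tolerates contained
# intervals (gap is measured to the rightmost end seen so far).
cummax_end <- function(end) cummax(end)

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d cluster(s) at gap threshold d = %g nt\n",
              length(x$clusters), x$d))
  for (i in seq_along(x$clusters)) {
    cl <- x$clusters[[i]]
    cat(sprintf("  [%d] %s:%d-%d  %d loci (%s)\n", i, cl$chrom[1],
                min(cl$start), max(cl$end), nrow(cl),
                paste(unique(cl$name), collapse = ",")))
  }
  invisible(x)
}

#' Per-chromosome, per-strand locus counts
#'
#' @param loci data.frame with columns `chrom` and `strand`.
#' @return data.frame with columns `chrom`, `plus`, `minus`; the grand
#'   total equals `nrow(loci)`.
#' @export
chrom_distribution <- function(loci) {
  if (nrow(loci) == 0) {
    return(data.frame(chrom = character(0), plus = integer(0),
                      minus = integer(0), stringsAsFactors = FALSE))
  }
  tab <- table(factor(loci$chrom), factor(loci$strand, levels = c("+", "-")))
  data.frame(chrom = rownames(tab), plus = as.integer(tab[, "+"]),
             minus = as.integer(tab[, "-"]), stringsAsFactors = FALSE)
}

# Coerce a genome given as character vector or DNAStringSet.
.as_genome <- function(genome) {
  if (is.character(genome)) {
    stopifnot(!is.null(names(genome)))
    genome <- Biostrings::DNAStringSet(.as_dna(genome))
  }
  stopifnot(methods::is(genome, "DNAStringSet"), !is.null(names(genome)))
  genome
}
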