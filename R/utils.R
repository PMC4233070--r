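#' @useDynLib mirfruit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnbinom runif p.adjust phyper pbinom setNames
#' @importFrom utils head read.delim write.table
NULL

# Stage labels used throughout: days after flowering.
.default_stages <- c("15DAF", "36DAF", "81DAF", "110DAF", "145DAF", "167DAF")

#' Reverse complement of a nucleotide string
#'
#' Accepts DNA or RNA alphabet (T and U are equivalent); returns the same
#' alphabet family as the input (U in -> U out).
#'
#' @param x character vector of nucleotide strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  has_u <- grepl("U", x, fixed = TRUE)
  xd <- chartr("U", "T", x)
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(xd)))
  out[has_u] <- chartr("T", "U", out[has_u])
  out
}

# Fast scalar reverse complement (DNA alphabet), for inner loops where
# constructing Biostrings objects would dominate.
.rc <- function(x) {
  vapply(x, function(s)
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
          collapse = ""), character(1), USE.NAMES = FALSE)
}

# Round half away from zero ("half-up" for positive values), the convention
# that reproduces published per-category averages such as x.5 -> x+1.
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Internal: normalize a sequence to DNA uppercase (U -> T).
.as_dna <- function(x) chartr("u", "T", chartr("U", "T", toupper(x)))

# Internal: validate nucleotide strings.
.check_nt <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTU]", .as_dna(x))
  if (any(bad)) {
    stop(sprintf("non-nucleotide characters in %s: %s",
                 what, paste(head(x[bad], 3), collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}
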