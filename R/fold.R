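#' Fold an RNA sequence into its minimum-energy nested structure
#'
#' Computes a secondary structure and its folding energy under an additive
#' base-pair energy model (GC = -3.0, AU = -2.0, GU = -1.0 kcal/mol) by
#' interval dynamic programming over nested structures with a minimum
#' hairpin loop of 3 unpaired nucleotides. The model is a deliberately
#' simple proxy for nearest-neighbour thermodynamics: energies are
#' comparable between sequences folded with the same backend, not with
#' published RNAfold values.
#'
#' The backend is pluggable: any function taking a sequence and returning
#' `list(structure = <balanced dot-bracket of equal length>, mfe = <= 0)`
#' can be substituted, e.g. to wire in an external thermodynamic folder.
#'
#' @param sequence single nucleotide string (A/C/G/T/U), length >= 10.
#' @param backend folding function; default is the built-in DP.
#' @return list with `structure` (dot-bracket string) and `mfe` (kcal/mol,
#'   <= 0).
#' @examples
#' fold_rna("GGGGAAAACCCC")
#' @export
fold_rna <- function(sequence, backend = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  if (nchar(sequence) < 10) {
    stop("sequence must be at least 10 nt long", call. = FALSE)
  }
  .check_nt(sequence)
  seq_dna <- .as_dna(sequence)
  res <- if (is.null(backend)) .fold_nussinov(seq_dna) else backend(seq_dna)
  if (!is.list(res) || is.null(res$structure) || is.null(res$mfe) ||
      nchar(res$structure) != nchar(sequence) || res$mfe > 0) {
    stop("folding backend returned an invalid (structure, mfe) pair",
         call. = FALSE)
  }
  res
}

# Parse a dot-bracket string into a pair table: integer vector p where
# p[i] = index of the partner of position i, or NA when unpaired.
pair_table <- function(structure) {
  chars <- strsplit(structure, "", fixed = TRUE)[[1]]
  n <- length(chars)
  p <- rep(NA_integer_, n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (length(stack) == 0) stop("unbalanced dot-bracket", call. = FALSE)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      p[j] <- i
      p[i] <- j
    } else if (chars[i] != ".") {
      stop("invalid dot-bracket character: ", chars[i], call. = FALSE)
    }
  }
  if (length(stack) > 0) stop("unbalanced dot-bracket", call. = FALSE)
  p
}

# Count terminal (hairpin) loops in a dot-bracket string and return their
# positions: a terminal loop is a maximal run of dots directly enclosed by
# a pair '(' ... ')' with no pairs inside.
terminal_loops <- function(structure) {
  m <- gregexpr("\\((\\.*)\\)", structure)[[1]]
  if (m[1] == -1) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  len <- attr(m, "match.length")
  data.frame(start = as.integer(m) + 1L, end = as.integer(m) + len - 2L)
}
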