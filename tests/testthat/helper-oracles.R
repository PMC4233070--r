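# Independent oracles used to cross-check the package implementation.
# Each is deliberately written with a different algorithm/decomposition
# than the code path it checks.

.oracle_pair_e <- function(a, b) {
  key <- paste0(a, b)
  if (key %in% c("GC", "CG")) return(-3)
  if (key %in% c("AT", "TA")) return(-2)
  if (key %in% c("GT", "TG")) return(-1)
  0
}

# Exhaustive enumeration of all nested structures with minimum loop 3;
# structures containing an isolated (lonely) pair are filtered out;
# returns the minimum total energy. Feasible for short sequences only
# (n <= ~14).
oracle_fold_enum <- function(seq) {
  s <- strsplit(chartr("U", "T", toupper(seq)), "")[[1]]
  n <- length(s)
  # all nested pair sets over [i, j] (lists of 2-column matrices)
  gen <- function(i, j) {
    if (j - i < 4) return(list(matrix(integer(0), ncol = 2)))
    out <- gen(i + 1, j)  # i unpaired
    for (k in seq.int(i + 4, j)) {
      if (.oracle_pair_e(s[i], s[k]) == 0) next
      for (inner in gen(i + 1, k - 1)) {
        for (outer in gen(k + 1, j)) {
          out[[length(out) + 1L]] <- rbind(c(i, k), inner, outer)
        }
      }
    }
    out
  }
  sets <- gen(1, n)
  best <- 0
  for (ps in sets) {
    if (nrow(ps) == 0) next
    key <- paste(ps[, 1], ps[, 2])
    lonely <- !(paste(ps[, 1] + 1, ps[, 2] - 1) %in% key |
                  paste(ps[, 1] - 1, ps[, 2] + 1) %in% key)
    if (any(lonely)) next
    e <- sum(mapply(function(a, b) .oracle_pair_e(s[a], s[b]),
                    ps[, 1], ps[, 2]))
    if (e < best) best <- e
  }
  best
}

# Independent interval recursion for the same model (no lonely pairs,
# minimum loop 3), memoised, decomposed from the RIGHT end — a different
# decomposition from the package DP. Works to ~30 nt.
oracle_fold_dp <- function(seq) {
  s <- strsplit(chartr("U", "T", toupper(seq)), "")[[1]]
  n <- length(s)
  if (n == 0) return(0)
  W <- matrix(NA_real_, n, n)
  P2 <- matrix(NA_real_, n, n)  # (i,j) paired, outer support present
  can <- function(i, j) j - i - 1 >= 3 && .oracle_pair_e(s[i], s[j]) != 0
  p2 <- function(i, j) {
    if (!can(i, j)) return(Inf)
    if (!is.na(P2[i, j])) return(P2[i, j])
    v <- .oracle_pair_e(s[i], s[j]) +
      min(w(i + 1, j - 1), p2(i + 1, j - 1))
    P2[i, j] <<- v
    v
  }
  w <- function(i, j) {
    if (i >= j) return(0)
    if (!is.na(W[i, j])) return(W[i, j])
    # decompose on j: j unpaired, or j pairs k (helix needs (k+1,j-1))
    v <- w(i, j - 1)
    for (k in if (j - 6 >= i) seq.int(i, j - 6) else integer(0)) {
      if (!can(k, j) || !can(k + 1, j - 1)) next
      cand <- .oracle_pair_e(s[k], s[j]) + p2(k + 1, j - 1) +
        (if (k - 1 >= i) w(i, k - 1) else 0)
      if (cand < v) v <- cand
    }
    W[i, j] <<- v
    v
  }
  w(1, n)
}

# Direct tail summation for the digital-count test: conditional on the
# total n = x + y, P(Y = k) = C(n, k) q^k (1-q)^(n-k) with
# q = N2/(N1+N2); two-sided by doubling the smaller tail (observation
# included), cap 1. Summation via log-gamma terms, no pbinom.
oracle_de_test <- function(x, y, n1, n2) {
  n <- x + y
  if (n == 0) return(1)
  q <- n2 / (n1 + n2)
  k <- 0:n
  logp <- lgamma(n + 1) - lgamma(k + 1) - lgamma(n - k + 1) +
    k * log(q) + (n - k) * log(1 - q)
  p <- exp(logp)
  lower <- sum(p[k <= y])
  upper <- sum(p[k >= y])
  min(1, 2 * min(lower, upper))
}

# Independently coded checker for the five target-prediction rules over
# a status weight matrix (0 match, 0.5 GU, 1 mismatch), one row per
# duplex. Uses string runs rather than column logic.
oracle_rules <- function(w) {
  apply(w, 1, function(v) {
    mm <- v == 1
    if (sum(v) > 4) return(FALSE)
    r <- rle(mm)
    if (any(r$lengths[r$values] > 2)) return(FALSE)
    for (i in 2:11) {
      if (i + 1 <= length(v) && mm[i] && mm[i + 1]) return(FALSE)
    }
    if (any(mm[10:min(11, length(v))])) return(FALSE)
    if (sum(v[1:min(12, length(v))]) > 2.5) return(FALSE)
    TRUE
  })
}

# O(n^2) transitive-closure clustering oracle: loci are linked when on
# the same chromosome with interval gap <= d; clusters are connected
# components with >= 2 members.
oracle_clusters <- function(loci, d) {
  n <- nrow(loci)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      if (loci$chrom[i] != loci$chrom[j]) next
      gap <- max(loci$start[i], loci$start[j]) -
        min(loci$end[i], loci$end[j])
      if (gap <= d) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comps <- split(seq_len(n), roots)
  comps <- Filter(function(ix) length(ix) >= 2, comps)
  # canonical form: sorted member row indices, sorted by first member
  out <- lapply(comps, function(ix) sort(ix))
  out[order(vapply(out, min, integer(1)))]
}

# Naive genome scan for exact occurrences of a pattern on both strands.
oracle_scan <- function(chrom_seq, pattern) {
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", pattern), "")[[1]]),
              collapse = "")
  hits <- function(pat) {
    L <- nchar(pat)
    starts <- integer(0)
    for (i in seq_len(nchar(chrom_seq) - L + 1)) {
      if (substr(chrom_seq, i, i + L - 1) == pat) starts <- c(starts, i)
    }
    starts
  }
  list(plus = hits(pattern), minus = hits(rc))
}

# Exhaustive hypergeometric upper tail by direct summation of choose().
oracle_hyper_upper <- function(k, K, N, n) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Shared small simulation config for fast module tests; `...` overrides
# the scaled-down defaults.
small_sim_config <- function(seed = 5, ...) {
  defaults <- list(seed = seed, n_chromosomes = 2L,
                   chromosome_length = 150000L, n_known_mirnas = 10L,
                   n_novel_precursors = 5L, n_planted_clusters = 2L,
                   reads_per_library = 2000L, n_genes = 10L,
                   n_repeats = 8L, n_ncrna = 6L, n_transcripts = 15L,
                   n_planted_targets = 8L)
  overrides <- list(...)
  defaults[names(overrides)] <- overrides
  do.call(sim_config, defaults)
}
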