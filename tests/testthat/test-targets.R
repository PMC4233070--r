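# Duplex scoring, the five complementarity rules, target search and
# enrichment factors.

rc <- function(x) revcomp(x)

test_that("duplex scoring: perfect complement, wobbles and core mismatches", {
  m <- "TTGACAGAAGAGAGTGAGCAC"  # 21 nt
  d0 <- score_duplex(m, rc(m))
  expect_equal(d0$total_mismatches, 0)
  expect_equal(d0$mismatches_10_11, 0)
  expect_true(all(d0$status == "match"))
  expect_true(passes_rules(d0))

  # single G:U at miRNA position 5 (miRNA C? position 5 is C -> use G/T)
  # position 5 of m is "C"; pick position 4 ("A"->no). Use position 2 "T":
  site <- rc(m)
  L <- nchar(m)
  p <- 5
  expect_equal(substr(m, p, p), "C")  # cannot wobble a C — use pos 6 "A"?
  # choose a position with G or T: position 1 is T
  p <- 1
  substr(site, L - p + 1, L - p + 1) <- "G"  # T:G wobble
  d1 <- score_duplex(m, site)
  expect_equal(d1$total_mismatches, 0.5)
  expect_equal(d1$mismatches_10_11, 0)
  expect_true(passes_rules(d1))

  # full mismatches at miRNA positions 10 and 11
  site2 <- rc(m)
  for (p in 10:11) {
    substr(site2, L - p + 1, L - p + 1) <- substr(m, p, p)
  }
  d2 <- score_duplex(m, site2)
  expect_equal(d2$mismatches_10_11, 2)
  expect_false(passes_rules(d2))

  expect_error(score_duplex(m, substr(rc(m), 1, 10)), "equal length")
})

test_that("rule boundaries: 4.0 total passes, 4.5 fails", {
  # 8 wobbles outside 1-12 would exceed L-12 positions; construct a
  # status matrix directly through the kernel to probe the boundary
  w4 <- matrix(0, 1, 21)
  w4[1, c(13, 15, 17, 19)] <- 1       # 4 full mismatches, isolated, late
  expect_true(as.logical(mirfruit:::rule_kernel(w4)))
  w45 <- w4; w45[1, 21] <- 0.5        # total 4.5
  expect_false(as.logical(mirfruit:::rule_kernel(w45)))
  # three adjacent full mismatches fail even when the total is small
  w3 <- matrix(0, 1, 21); w3[1, 15:17] <- 1
  expect_false(as.logical(mirfruit:::rule_kernel(w3)))
  # adjacent pair inside 2-12 fails; the same pair at 13-14 passes
  wa <- matrix(0, 1, 21); wa[1, 5:6] <- 1
  expect_false(as.logical(mirfruit:::rule_kernel(wa)))
  wb <- matrix(0, 1, 21); wb[1, 13:14] <- 1
  expect_true(as.logical(mirfruit:::rule_kernel(wb)))
  # weighted 1-12 cap: five wobbles (2.5) pass, six (3.0) fail
  wc <- matrix(0, 1, 21); wc[1, c(1, 3, 5, 7, 9)] <- 0.5
  expect_true(as.logical(mirfruit:::rule_kernel(wc)))
  wd <- wc; wd[1, 12] <- 0.5
  expect_false(as.logical(mirfruit:::rule_kernel(wd)))
})

test_that("rules agree with the independent checker on random vectors", {
  set.seed(21)
  w <- matrix(sample(c(0, 0.5, 1), 21 * 4000, replace = TRUE,
                     prob = c(0.7, 0.15, 0.15)), ncol = 21)
  expect_equal(unname(mirfruit:::rule_kernel(w)), unname(oracle_rules(w)))
})

test_that("adding a full mismatch never converts a failing duplex to passing", {
  set.seed(22)
  for (i in 1:200) {
    w <- numeric(21)
    k <- sample(0:5, 1)
    if (k > 0) w[sample(21, k)] <- sample(c(0.5, 1), k, replace = TRUE)
    before <- as.logical(mirfruit:::rule_kernel(matrix(w, 1)))
    free <- which(w == 0)
    if (length(free) == 0) next
    w2 <- w; w2[sample(free, 1)] <- 1
    after <- as.logical(mirfruit:::rule_kernel(matrix(w2, 1)))
    expect_false(!before && after)
  }
})

test_that("find_targets locates planted sites and rejects core-mismatch sites", {
  set.seed(23)
  m <- c(mirA = "TGGAGAAGCAGGGCACGTGCA")
  tx_bg <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                 collapse = "")
  good <- rc(m[["mirA"]])
  bad <- rc(m[["mirA"]])
  substr(bad, 21 - 10 + 1, 21 - 10 + 1) <- substr(m[["mirA"]], 10, 10)
  tx <- c(t1 = paste0(substr(tx_bg, 1, 100), good, substr(tx_bg, 101, 200)),
          t2 = paste0(substr(tx_bg, 1, 100), bad, substr(tx_bg, 101, 200)),
          t3 = "ACGT")  # shorter than the miRNA: skipped
  res <- find_targets(m, tx)
  expect_true(any(res$sites$transcript == "t1" & res$sites$start == 101))
  expect_false(any(res$sites$transcript == "t2" & res$sites$start == 101))
  expect_equal(unname(res$target_counts["mirA"]), 1L)
})

test_that("enrichment factor is (k/n)/(K/N) with a hypergeometric tail", {
  ann <- data.frame(gene = c(paste0("g", 1:20), paste0("g", 1:5)),
                    term = c(rep("T1", 20), rep("T2", 5)))
  universe <- paste0("g", 1:400)
  # k/n = K/N gives EF 1
  r1 <- enrichment(paste0("g", 1:20), ann, universe, adjust = FALSE)
  expect_equal(r1$enrichment_factor[r1$term == "T1"], 20 / 20 / (20 / 400))
  # closed form: k=5, n=10, K=20, N=400 -> EF 10
  targ <- c(paste0("g", 1:5), paste0("g", 100:104))
  r2 <- enrichment(targ, ann, universe, adjust = FALSE)
  row <- r2[r2$term == "T1", ]
  expect_equal(row$enrichment_factor, (5 / 10) / (20 / 400))
  expect_equal(row$pvalue, oracle_hyper_upper(5, 20, 400, 10))
  # p-values equal exhaustive summation on random small instances
  set.seed(24)
  for (i in 1:20) {
    N <- sample(50:200, 1); K <- sample(5:30, 1)
    n <- sample(5:30, 1); k <- sample(0:min(K, n), 1)
    expect_equal(phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 oracle_hyper_upper(k, K, N, n))
  }
  expect_error(enrichment("gX", ann, universe), "universe")
})
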