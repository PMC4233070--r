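# Conserved-miRNA matching, window excision, hairpin criteria and novel
# prediction.

test_that("known matching is exact with T/U equivalence", {
  ref <- c("pyr-miR156a" = "TGACAGAAGAGAGTGAGCAC",
           "pyr-miR397a" = "UCAUUGAGUGCAGCGUUGAUG")
  cl <- structure(list(
    library_id = "15DAF",
    records = data.frame(
      sequence = c("TGACAGAAGAGAGTGAGCAC",       # exact
                   "TCATTGAGTGCAGCGTTGATG",      # exact after U->T
                   "TGACAGAAGAGAGTGAGCAT"),      # 1 mismatch: unmatched
      count = c(10L, 5L, 7L)),
    total_raw = 22L, total_clean = 22L), class = "clean_read_set")
  res <- match_known(cl, ref)
  expect_equal(unname(res$counts["pyr-miR156a", "15DAF"]), 10)
  expect_equal(unname(res$counts["pyr-miR397a", "15DAF"]), 5)
  expect_equal(res$unmatched[["15DAF"]]$sequence,
               "TGACAGAAGAGAGTGAGCAT")
  expect_setequal(res$matched$family, c("miR156", "miR397"))
  expect_error(match_known(cl, setNames(ref, c("a", "a"))), "unique")
})

test_that("family names follow miRBase stripping conventions", {
  expect_equal(mirna_family(c("pbr-miR156k", "miR4414a*", "miR396b-3p",
                              "ath-miR172", "miR827")),
               c("miR156", "miR4414", "miR396", "miR172", "miR827"))
})

test_that("excised windows are verbatim genome substrings with clipping flags", {
  set.seed(51)
  g <- c(chr1 = paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
                      collapse = ""))
  loci <- data.frame(chrom = "chr1", start = c(500, 10), end = c(520, 30),
                     strand = c("+", "-"))
  wins <- excise_candidates(g, loci, flank = 150)
  for (r in seq_len(nrow(wins))) {
    sub <- substr(g[[1]], wins$win_start[r], wins$win_end[r])
    if (wins$strand[r] == "-") sub <- revcomp(sub)
    expect_equal(wins$window[r], sub)
    # the mature offset points at the read within the window
    expect_equal(substr(wins$window[r], wins$mature_offset[r] + 1,
                        wins$mature_offset[r] + 21),
                 if (wins$strand[r] == "-") {
                   revcomp(substr(g[[1]], wins$start[r], wins$end[r]))
                 } else {
                   substr(g[[1]], wins$start[r], wins$end[r])
                 })
  }
  # the read 10 nt from the start is clipped at the chromosome bound
  up <- wins[wins$start == 10 & wins$side == "up", ]
  expect_true(up$clipped)
  expect_equal(up$win_start, 1L)
})

test_that("hairpin criteria accept a planted precursor and reject variants", {
  set.seed(52)
  hp <- mirfruit:::.build_precursor(mature_arm = "5p", n_noise = 1)
  ev <- evaluate_hairpin(hp$precursor, hp$mature_offset, nchar(hp$mature))
  expect_true(ev$accept)
  expect_true(all(ev$flags))
  expect_equal(ev$mature_arm, "5p")
  # the mature is a substring of the reported precursor
  expect_true(grepl(hp$mature, ev$precursor, fixed = TRUE))

  # a 60-nt candidate fails the length criterion
  short_arm <- mirfruit:::.build_precursor(arm_len = 24L, loop_len = 12L,
                                           mature_len = 21L,
                                           mature_offset = 0L,
                                           mature_arm = "5p", n_noise = 0)
  expect_lte(nchar(short_arm$precursor), 63)
  ev2 <- evaluate_hairpin(short_arm$precursor, short_arm$mature_offset,
                          nchar(short_arm$mature))
  expect_false(ev2$flags[["length_ok"]])
  expect_false(ev2$accept)

  # destroying the star arm (random sequence) removes mature pairing
  broken <- paste0(substr(hp$precursor, 1, 70),
                   paste(sample(c("A", "C"), nchar(hp$precursor) - 70,
                                replace = TRUE), collapse = ""))
  ev3 <- evaluate_hairpin(broken, hp$mature_offset, nchar(hp$mature))
  expect_false(ev3$accept)
})

test_that("novel prediction recovers planted precursors, rejects noise, and is monotone in the MFE threshold", {
  set.seed(53)
  cfg <- small_sim_config(seed = 53)
  g <- generate_genome(cfg)
  np <- g$truth$novel_precursors
  # per-library records: each planted novel mature observed 2+2 times,
  # plus unique noise sequences below min_count
  noise <- vapply(1:30, function(i)
    paste(sample(c("A", "C", "G", "T"), 22, replace = TRUE),
          collapse = ""), character(1))
  records <- list(
    L1 = data.frame(sequence = c(np$mature, noise),
                    count = c(rep(2L, nrow(np)), rep(1L, 30))),
    L2 = data.frame(sequence = np$mature, count = rep(2L, nrow(np))))
  res <- predict_novel(records, g$genome)
  expect_gte(mean(np$mature %in% res$novel$sequence), 0.8)
  expect_true(all(res$novel$sequence %in% np$mature))
  # every accepted mature is a substring of its precursor, which is a
  # verbatim genome substring (mod strand)
  for (r in seq_len(nrow(res$novel))) {
    expect_true(grepl(res$novel$sequence[r], res$novel$precursor[r],
                      fixed = TRUE))
    expect_true(grepl(
      if (res$novel$strand[r] == "-") revcomp(res$novel$precursor[r])
      else res$novel$precursor[r],
      g$genome[[res$novel$chrom[r]]], fixed = TRUE))
  }
  # counts matrix aligns with the input records
  expect_equal(dim(res$counts), c(nrow(res$novel), 2))
  # relaxing the MFE threshold never decreases the accepted count
  n_strict <- nrow(predict_novel(records, g$genome, mfe_max = -40)$novel)
  n_loose <- nrow(predict_novel(records, g$genome, mfe_max = -10)$novel)
  expect_lte(n_strict, n_loose)
  # no candidate input: empty result
  empty <- predict_novel(list(L1 = data.frame(sequence = character(0),
                                              count = integer(0))),
                         g$genome)
  expect_equal(nrow(empty$novel), 0)
})

test_that("known and novel sets stay disjoint by sequence", {
  set.seed(54)
  cfg <- small_sim_config(seed = 54)
  g <- generate_genome(cfg)
  # feed known sequences into novel prediction with the reference as the
  # exclusion set: none may be called novel
  records <- list(L1 = data.frame(sequence = unname(g$known_ref),
                                  count = rep(5L, length(g$known_ref))))
  res <- predict_novel(records, g$genome, exclude = g$known_ref)
  expect_false(any(res$novel$sequence %in% g$known_ref))
})
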