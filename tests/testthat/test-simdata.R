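# Synthetic study generator: determinism, planting retrievability,
# cluster geometry, library composition and target-site registry.

test_that("config invariants are enforced", {
  expect_error(sim_config(reads_per_library = 10), "reads_per_library")
  expect_error(sim_config(contaminant_fraction = 1.2))
  expect_error(sim_config(cluster_span = 1e9))
})

test_that("planted mature sequences are retrievable at their recorded loci", {
  cfg <- small_sim_config(seed = 61)
  g <- generate_genome(cfg)
  loci <- g$truth$mirna_loci
  for (r in seq_len(nrow(loci))) {
    sub <- substr(g$genome[[loci$chrom[r]]], loci$start[r], loci$end[r])
    if (loci$strand[r] == "-") sub <- revcomp(sub)
    expect_equal(sub, unname(g$truth$mature_sequences[[loci$name[r]]]),
                 info = loci$name[r])
  }
  # every planted precursor's mature arm is a substring of its window
  np <- g$truth$novel_precursors
  expect_true(all(mapply(grepl, np$mature, np$precursor, fixed = TRUE)))
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- small_sim_config(seed = 62)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1$genome, g2$genome)
  expect_identical(g1$truth, g2$truth)
  l1 <- simulate_libraries(g1$genome, g1$truth, g1$annotation, g1$ncrna, cfg)
  l2 <- simulate_libraries(g2$genome, g2$truth, g2$annotation, g2$ncrna, cfg)
  expect_identical(l1$libraries, l2$libraries)
  expect_identical(l1$truth_counts, l2$truth_counts)
  # byte-identical FASTQ streams
  f1 <- tempfile(); f2 <- tempfile()
  write_fastq(l1$libraries[[1]], f1)
  write_fastq(l2$libraries[[1]], f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("a genome too small for the requested loci raises a capacity error", {
  cfg <- small_sim_config(seed = 63)
  cfg$chromosome_length <- 3000L
  cfg$cluster_span <- 1000L
  expect_error(generate_genome(cfg), "too short")
})

test_that("planted clusters satisfy the distance geometry (O(n^2) check)", {
  cfg <- small_sim_config(seed = 64)
  g <- generate_genome(cfg)
  loci <- g$truth$mirna_loci
  for (tc in g$truth$true_clusters) {
    members <- loci[loci$source == "known_cluster_copy" &
                      loci$chrom == tc$chrom &
                      loci$name %in% tc$members &
                      loci$start %in% tc$starts, ]
    expect_equal(nrow(members), 2)
    # brute-force pairwise gap within the planted span
    gap <- max(members$start) - min(members$end) - 1
    expect_lte(gap, cfg$cluster_span)
  }
})

test_that("library truth counts equal the planted-origin reads written", {
  cfg <- small_sim_config(seed = 65)
  sim <- simulate_srna_study(cfg)
  for (st in names(sim$libraries)) {
    rc <- sim$read_classes[[st]]
    expect_equal(sum(rc$n), nrow(sim$libraries[[st]]))
    expect_equal(rc$n[rc$class == "mirna"],
                 sum(sim$truth_counts[, st]))
  }
})

test_that("with no contaminants every cleaned read is a planted mature", {
  cfg <- small_sim_config(seed = 66, contaminant_fraction = 0)
  sim <- simulate_srna_study(cfg)
  cl <- clean_reads(sim$libraries[[1]], cfg$adapter_3p, library_id = "x")
  expect_true(all(cl$records$sequence %in% sim$truth$mature_sequences))
  expect_equal(cl$total_clean, cl$total_raw)
})

test_that("flat stage profiles give stage counts compatible with equal means", {
  # near-Poisson dispersion so the chi-square equal-proportion test applies
  cfg <- small_sim_config(seed = 67, n_de_up = 0L, n_de_down = 0L,
                          nb_dispersion = 1e6,
                          reads_per_library = 20000L)
  sim <- simulate_srna_study(cfg)
  counts <- sim$truth_counts[1, ]
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("degraded-quality mode produces reads the quality filter removes", {
  cfg <- small_sim_config(seed = 68, degraded_quality_fraction = 0.2)
  sim <- simulate_srna_study(cfg)
  cl <- clean_reads(sim$libraries[[1]], cfg$adapter_3p)
  expect_equal(cl$total_clean, sum(sim$read_classes[[1]]$survivors))
  expect_lt(cl$total_clean, cl$total_raw * 0.9)
})

test_that("planted target sites honour edit sets and compliance validation", {
  cfg <- small_sim_config(seed = 69)
  g <- generate_genome(cfg)
  tx <- generate_transcripts(g$truth, cfg)
  reg <- tx$registry
  expect_equal(nrow(reg), cfg$n_planted_targets)
  for (r in seq_len(nrow(reg))) {
    m <- g$truth$mature_sequences[[reg$mirna[r]]]
    site <- substr(tx$transcripts[[reg$transcript[r]]], reg$position[r],
                   reg$position[r] + nchar(m) - 1)
    d <- score_duplex(m, site)
    # edit-free sites are exact reverse complements
    if (reg$wobble_at[r] == "" && reg$mismatch_at[r] == "") {
      expect_equal(d$total_mismatches, 0)
    }
    # registry compliance equals the rule decision on the planted site
    expect_equal(passes_rules(d), reg$compliant[r], info = r)
  }
  # a planted G:U at miRNA position 5 scores exactly 0.5
  m5 <- names(which(vapply(g$truth$mature_sequences, function(s)
    substr(mirfruit:::.as_dna(s), 5, 5) %in% c("G", "T"), logical(1))))[1]
  spec1 <- data.frame(mirna = m5, wobble_at = "5", mismatch_at = "")
  tx1 <- generate_transcripts(g$truth, cfg, site_specs = spec1)
  r1 <- tx1$registry
  site <- substr(tx1$transcripts[[r1$transcript]], r1$position,
                 r1$position + nchar(g$truth$mature_sequences[[m5]]) - 1)
  expect_equal(score_duplex(g$truth$mature_sequences[[m5]],
                            site)$total_mismatches, 0.5)
  # a mismatch at position 10 must register as rule-violating
  spec2 <- data.frame(mirna = m5, wobble_at = "", mismatch_at = "10")
  expect_false(generate_transcripts(g$truth, cfg,
                                    site_specs = spec2)$registry$compliant)
  # contradicting the computed compliance is an error
  spec3 <- data.frame(mirna = m5, wobble_at = "", mismatch_at = "10",
                      compliant = TRUE)
  expect_error(generate_transcripts(g$truth, cfg, site_specs = spec3),
               "contradicts")
})

test_that("write_simdata emits the standard file set", {
  cfg <- small_sim_config(seed = 70)
  sim <- simulate_srna_study(cfg)
  out <- file.path(tempdir(), "simout")
  write_simdata(sim, out)
  expect_true(all(file.exists(file.path(out,
    c("genome.fa", "annotation.gff3", "ncrna.fa", "known_mirnas.fa",
      "transcripts.fa", "lib_15DAF.fastq",
      file.path("truth", "mirna_loci.tsv"))))))
  g <- Biostrings::readDNAStringSet(file.path(out, "genome.fa"))
  expect_equal(length(g), cfg$n_chromosomes)
  unlink(out, recursive = TRUE)
})
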