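# Read cleaning, collapsing, categorization and library summaries.

adapter <- "TGGAATTCTCGGGTGCCAAGG"
hi_q <- function(n) strrep("I", n)

mk_reads <- function(seqs, quals = NULL) {
  if (is.null(quals)) quals <- vapply(nchar(seqs), hi_q, character(1))
  data.frame(sequence = seqs, quality = quals, stringsAsFactors = FALSE)
}

test_that("adapter removal, poly-A, quality and length filters", {
  insert21 <- "ACGTACGTACGTACGTACGTA"
  insert17 <- "ACGTACGTACGTACGTA"
  polya <- "AAAAAAAAAAAAAAAAAAAA"
  reads <- mk_reads(c(
    paste0(insert21, adapter),                       # kept, trimmed
    paste0(insert17, adapter),                       # < 18 nt: dropped
    paste0(polya, adapter),                          # poly-A: dropped
    strrep("C", 36),                                 # no adapter: 36 nt, dropped
    paste0(insert21, substr(adapter, 1, 6))          # 6-nt overlap: kept
  ))
  cl <- clean_reads(reads, adapter)
  expect_equal(cl$total_raw, 5)
  expect_equal(cl$total_clean, 2)
  expect_equal(cl$records$sequence, insert21)
  expect_equal(cl$records$count, 2L)

  # low mean quality discards the read
  lowq <- mk_reads(paste0(insert21, adapter),
                   quals = strrep("#", 21 + nchar(adapter)))
  expect_equal(clean_reads(lowq, adapter)$total_clean, 0)
})

test_that("cleaning is idempotent at the sequence-set level", {
  set.seed(41)
  inserts <- vapply(1:50, function(i)
    paste(sample(c("A", "C", "G", "T"), sample(18:28, 1), replace = TRUE),
          collapse = ""), character(1))
  inserts <- inserts[!grepl(substr(adapter, 1, 6), inserts, fixed = TRUE)]
  reads <- mk_reads(substr(paste0(inserts, adapter), 1, 36))
  cl1 <- clean_reads(reads, adapter)
  # feed the cleaned unique sequences back through (as adapterless reads)
  again <- mk_reads(cl1$records$sequence)
  cl2 <- clean_reads(again, adapter)
  expect_setequal(cl2$records$sequence, cl1$records$sequence)
  # collapsing preserves the total read number
  expect_equal(sum(cl1$records$count), cl1$total_clean)
})

test_that("malformed FASTQ is reported with a line number", {
  tmp <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "III"), tmp)  # quality too short
  expect_error(read_fastq(tmp), "line 2")
  writeLines(c("r1", "ACGT", "+", "IIII"), tmp)
  expect_error(read_fastq(tmp), "line 1")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2"), tmp)
  expect_error(read_fastq(tmp), "multiple of 4")
})

test_that("FASTQ round-trips through write and read, including file input", {
  reads <- mk_reads(c(paste0(strrep("ACGTT", 5), adapter)))
  reads$id <- "r1"
  tmp <- tempfile(fileext = ".fastq")
  write_fastq(reads, tmp)
  back <- read_fastq(tmp)
  expect_equal(back$sequence, reads$sequence)
  cl <- clean_reads(tmp, adapter)
  expect_equal(cl$records$sequence, strrep("ACGTT", 5))
})

test_that("categorization uses the fixed priority order and partitions reads", {
  exon_seq <- "GATTACAGATTACAGATTACA"     # planted inside an exon
  known <- c(mir1 = "TTGACAGAAGAGAGTGAGCAC")
  nc <- c(nc1 = "CCCGGGAAATTTCCCGGGAAATTTCCCGGGTTTAAA")
  set.seed(42)
  bg <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
              collapse = "")
  genome <- c(chr1 = paste0(substr(bg, 1, 1000), exon_seq,
                            substr(bg, 1001, 2000), known[["mir1"]],
                            substr(bg, 2001, 3000)))
  annotation <- list(
    exons = GenomicRanges::GRanges("chr1",
      IRanges::IRanges(995, 1030), strand = "+"),
    introns = GenomicRanges::GRanges(),
    repeats = GenomicRanges::GRanges())
  # the known miRNA ALSO sits inside an exon when we annotate it as such:
  annotation$exons <- c(annotation$exons,
    GenomicRanges::GRanges("chr1", IRanges::IRanges(2015, 2045),
                           strand = "+"))
  reads <- mk_reads(substr(paste0(
    c(known[["mir1"]],                       # known even though exonic
      exon_seq,                              # exon_sense
      revcomp(exon_seq),                     # exon_antisense
      substr(nc[["nc1"]], 3, 24),            # ncRNA decoy substring
      strrep("GTCA", 6)),                    # unannotated
    adapter), 1, 36))
  cl <- clean_reads(reads, adapter)
  st <- categorize(cl, nc, genome, annotation, known)
  expect_equal(unname(st$categories["known_mirna"]), 1)
  expect_equal(unname(st$categories["exon_sense"]), 1)
  expect_equal(unname(st$categories["exon_antisense"]), 1)
  expect_equal(unname(st$categories["rrna_etc"]), 1)
  expect_equal(unname(st$categories["unannotated"]), 1)
  expect_equal(sum(st$categories), st$clean_reads)
})

test_that("length distribution and first-base bias are count-weighted", {
  cl <- structure(list(
    library_id = "x",
    records = data.frame(
      sequence = c("TTGACAGAAGAGAGTGAGCAC",   # 21 nt, starts T/U
                   "ACGACAGAAGAGAGTGAGCAC",   # 21 nt, starts A
                   "ACGTACGTACGTACGTACGTACGT"), # 24 nt
      count = c(3L, 1L, 4L)),
    total_raw = 8L, total_clean = 8L), class = "clean_read_set")
  ld <- length_distribution(cl)
  expect_equal(unname(ld["21"]), 0.5)
  expect_equal(unname(ld["24"]), 0.5)
  expect_equal(sum(ld), 1)
  bb <- first_base_bias(cl, 21)
  expect_equal(unname(bb["U"]), 0.75)
  expect_equal(unname(bb["A"]), 0.25)
  expect_equal(sum(bb), 1)
  # no sequence of the stated length: NA signal, not an error
  expect_true(all(is.na(first_base_bias(cl, 30))))
})

test_that("aggregation reproduces half-up averages and pooled percentages", {
  # single library: averages equal that library's values
  one <- matrix(c(100, 90, 10, 20, 60), ncol = 1,
                dimnames = list(c("total_reads", "clean_reads",
                                  "rrna_etc", "known_mirna",
                                  "unannotated"), "L1"))
  agg1 <- aggregate_stats(one)
  expect_equal(unname(agg1$table[, "Average"]), unname(one[, 1]))
  expect_equal(agg1$pooled_clean_pct, 90)
  # half-up rounding: mean 8,596,938.5 must become 8,596,939
  expect_equal(mirfruit:::round_half_up(8596938.5), 8596939)
  expect_equal(mirfruit:::round_half_up(1217956.83), 1217957)
})
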