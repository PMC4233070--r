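#' Run the full small-RNA analysis pipeline
#'
#' Cleans every library, categorizes reads, identifies conserved miRNAs
#' by exact reference matching, predicts novel miRNAs from unannotated
#' reads, quantifies and tests differential expression against the
#' control stage, maps identified matures to the genome, detects
#' genomic clusters, and predicts transcript targets.
#'
#' @param sim a study bundle as produced by [simulate_srna_study()] (or
#'   an equivalently shaped list of real inputs: `libraries`, `genome`,
#'   `annotation`, `ncrna`, `known_ref`, `transcripts`).
#' @param adapter_3p 3' adapter for cleaning.
#' @param control control stage label for differential expression.
#' @param cluster_d cluster gap threshold(s) in nt (default 10000).
#' @param quality_threshold mean Phred threshold for cleaning.
#' @param min_count minimum summed read count for novel candidates.
#' @return list with elements `clean` (per-library `clean_read_set`),
#'   `stats` (per-library `library_stats`), `aggregate`, `known`
#'   ([match_known()] output), `novel` ([predict_novel()] output), `de`
#'   ([de_table()] output over known + novel counts), `loci` (mapped
#'   genomic loci of all identified matures), `clusters` (per `cluster_d`
#'   value), `chrom_dist`, `targets` ([find_targets()] output),
#'   `lengths` (per-library length distributions) and `base_bias`.
#' @export
run_pipeline <- function(sim, adapter_3p = "TGGAATTCTCGGGTGCCAAGG",
                         control = "15DAF", cluster_d = 10000,
                         quality_threshold = 20, min_count = 3L) {
  clean <- lapply(names(sim$libraries), function(st)
    clean_reads(sim$libraries[[st]], adapter_3p,
                quality_threshold = quality_threshold, library_id = st))
  names(clean) <- names(sim$libraries)
  stats <- lapply(clean, function(cl)
    categorize(cl, sim$ncrna, sim$genome, sim$annotation, sim$known_ref))
  aggregate <- aggregate_stats(unname(stats))
  known <- match_known(unname(clean), sim$known_ref)

  # novel prediction input: unmatched reads in the unannotated category
  unannotated <- lapply(names(clean), function(st) {
    rec <- known$unmatched[[st]]
    cat_of <- stats[[st]]$category_of
    rec[cat_of[rec$sequence] == "unannotated", , drop = FALSE]
  })
  names(unannotated) <- names(clean)
  novel <- predict_novel(unannotated, sim$genome, min_count = min_count,
                         exclude = sim$known_ref)

  totals <- vapply(clean, function(x) x$total_clean, numeric(1))
  counts <- known$counts
  if (!is.null(novel$counts) && nrow(novel$counts) > 0) {
    counts <- rbind(counts, novel$counts[, colnames(counts), drop = FALSE])
  }
  de <- de_table(counts, totals, control = control)

  matures <- c(setNames(known$matched$sequence, known$matched$name),
               setNames(novel$novel$sequence, novel$novel$name))
  loci <- map_mature_set(sim$genome, matures)
  clusters <- lapply(cluster_d, function(d) detect_clusters(loci, d))
  names(clusters) <- as.character(cluster_d)

  targets <- if (!is.null(sim$transcripts)) {
    find_targets(matures, sim$transcripts)
  }
  list(clean = clean, stats = stats, aggregate = aggregate,
       known = known, novel = novel, de = de, loci = loci,
       clusters = clusters, chrom_dist = chrom_distribution(loci),
       targets = targets,
       lengths = lapply(clean, length_distribution),
       base_bias = lapply(clean, first_base_bias))
}
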