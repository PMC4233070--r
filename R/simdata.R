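# Synthetic small-RNA study generator: a genome with planted miRNA loci,
# gene/repeat annotation, ncRNA decoys, staged sequencing libraries with
# known ground truth, and transcripts with planted target sites. Every
# downstream stage of the pipeline is testable against the recorded truth
# without any external download.

#' Configuration for a synthetic small-RNA study
#'
#' Defaults emulate a six-stage fruit-development study at desk scale:
#' six libraries (15/36/81/110/145/167 days after flowering), 50,000
#' reads per library (the sequenced study was ~20M; depth is scaled down
#' explicitly), read lengths centred on 21-24 nt with 24 nt most
#' frequent, a U-biased first nucleotide, a 3' sequencing adapter, and a
#' contaminant mix of ncRNA, repeat, gene-derived, intergenic, poly-A and
#' sub-18-nt reads. Counts are negative binomial (overdispersed) around
#' stage-profile means; a subset of miRNAs carries a planted monotone
#' 8-fold abundance trend across stages.
#'
#' @param seed integer RNG seed (derived seeds stay near this value).
#' @param n_chromosomes,chromosome_length genome shape.
#' @param n_known_mirnas,n_novel_precursors planted miRNA counts.
#' @param n_planted_clusters,cluster_span genomic cluster planting.
#' @param stage_labels library labels, in developmental order.
#' @param reads_per_library sequencing depth per library (>= 1000).
#' @param read_length raw read length in nt.
#' @param adapter_3p 3' adapter appended to every insert.
#' @param nb_dispersion negative binomial size parameter (> 0).
#' @param contaminant_fraction fraction of non-miRNA reads, in [0, 1).
#' @param n_de_up,n_de_down known miRNAs with planted monotone 8-fold
#'   increase / decrease across stages.
#' @param de_fold planted fold change between first and last stage.
#' @param n_genes,n_repeats,n_ncrna annotation/decoy richness.
#' @param n_transcripts,n_planted_targets target-prediction substrate.
#' @param degraded_quality_fraction fraction of reads given low base
#'   qualities (mean Phred < 20), to exercise the quality filter.
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 4L,
                       chromosome_length = 500000L,
                       n_known_mirnas = 30L,
                       n_novel_precursors = 20L,
                       n_planted_clusters = 3L,
                       cluster_span = 10000L,
                       stage_labels = c("15DAF", "36DAF", "81DAF",
                                        "110DAF", "145DAF", "167DAF"),
                       reads_per_library = 50000L,
                       read_length = 36L,
                       adapter_3p = "TGGAATTCTCGGGTGCCAAGG",
                       nb_dispersion = 5,
                       contaminant_fraction = 0.25,
                       n_de_up = 5L, n_de_down = 5L, de_fold = 8,
                       n_genes = 30L, n_repeats = 20L, n_ncrna = 15L,
                       n_transcripts = 60L, n_planted_targets = 25L,
                       degraded_quality_fraction = 0) {
  cfg <- list(seed = as.integer(seed), n_chromosomes = n_chromosomes,
              chromosome_length = chromosome_length,
              n_known_mirnas = n_known_mirnas,
              n_novel_precursors = n_novel_precursors,
              n_planted_clusters = n_planted_clusters,
              cluster_span = cluster_span, stage_labels = stage_labels,
              n_stages = length(stage_labels),
              reads_per_library = reads_per_library,
              read_length = read_length, adapter_3p = adapter_3p,
              nb_dispersion = nb_dispersion,
              contaminant_fraction = contaminant_fraction,
              n_de_up = n_de_up, n_de_down = n_de_down, de_fold = de_fold,
              n_genes = n_genes, n_repeats = n_repeats, n_ncrna = n_ncrna,
              n_transcripts = n_transcripts,
              n_planted_targets = n_planted_targets,
              degraded_quality_fraction = degraded_quality_fraction)
  stopifnot(cfg$reads_per_library >= 1000,
            cfg$contaminant_fraction >= 0, cfg$contaminant_fraction < 1,
            cfg$degraded_quality_fraction >= 0,
            cfg$degraded_quality_fraction < 1,
            cfg$nb_dispersion > 0,
            cfg$cluster_span <= cfg$chromosome_length,
            cfg$n_stages >= 2, nchar(cfg$adapter_3p) >= 6)
  class(cfg) <- "sim_config"
  cfg
}

# Mature-length sampler: 24 nt most frequent, then 23, 21, 20 — the
# canonical plant small-RNA profile (21-24 nt carry ~90%).
.mature_length_probs <- c(`18` = 0.02, `19` = 0.02, `20` = 0.06,
                          `21` = 0.15, `22` = 0.08, `23` = 0.22,
                          `24` = 0.45)

# Contaminant fragment lengths follow the same gel size selection as the
# miRNA inserts (18-30 nt libraries with 21-24 nt dominating), so the
# library-wide length profile matches the study design.
.frag_length_probs <- c(`18` = 0.02, `19` = 0.02, `20` = 0.05,
                        `21` = 0.15, `22` = 0.09, `23` = 0.21,
                        `24` = 0.40, `25` = 0.03, `26` = 0.01,
                        `27` = 0.01, `28` = 0.01)

.frag_len <- function(n = 1) {
  sample(as.integer(names(.frag_length_probs)), n, replace = TRUE,
         prob = .frag_length_probs)
}

# Random mature sequence with a U-biased first nucleotide. Rejects
# candidates that contain `avoid` (the adapter seed, so simulated reads
# trim unambiguously) or that would trip the poly-A filter.
.random_mature <- function(len, avoid = NULL) {
  repeat {
    first <- sample(c("T", "A", "G", "C"), 1,
                    prob = c(0.37, 0.31, 0.18, 0.14))
    rest <- sample(c("A", "C", "G", "T"), len - 1, replace = TRUE)
    x <- paste0(first, paste(rest, collapse = ""))
    frac_a <- (nchar(x) - nchar(gsub("A", "", x, fixed = TRUE))) / nchar(x)
    if (frac_a >= 0.8) next
    if (!is.null(avoid) && grepl(avoid, x, fixed = TRUE)) next
    return(x)
  }
}

# Draw from `gen` until the result does not contain `avoid`.
.sample_clean <- function(gen, avoid, tries = 200L) {
  for (i in seq_len(tries)) {
    x <- gen()
    if (is.null(avoid) || !grepl(avoid, x, fixed = TRUE)) return(x)
  }
  x
}

# Interval placement with collision avoidance; occ is an environment
# holding a data.frame of occupied intervals.
.place <- function(occ, chrom_len, n_chrom, len, buffer = 400L,
                   chrom = NULL) {
  for (try in 1:2000) {
    ch <- if (is.null(chrom)) sample.int(n_chrom, 1) else chrom
    s <- sample.int(chrom_len - len - buffer, 1) + buffer %/% 2L
    e <- s + len - 1L
    o <- occ$tab
    clash <- any(o$chrom == ch & o$start <= e + buffer & o$end >= s - buffer)
    if (!clash) {
      occ$tab <- rbind(o, data.frame(chrom = unname(ch), start = unname(s),
                                     end = unname(e)))
      return(setNames(as.integer(c(ch, s, e)), c("chrom", "start", "end")))
    }
  }
  stop("chromosomes too short to host the requested loci", call. = FALSE)
}

# Build a hairpin precursor: 5' arm + loop (A/C only, so the loop cannot
# pair internally) + reverse complement of the arm with `n_noise`
# substitutions. The mature sits inside one arm at the given offset.
.build_precursor <- function(arm_len = 55L, loop_len = 15L,
                             mature_len = 21L, mature_offset = NULL,
                             mature_arm = c("5p", "3p"), n_noise = 1L,
                             avoid = NULL) {
  mature_arm <- match.arg(mature_arm)
  if (is.null(mature_offset)) {
    mature_offset <- sample(5:(arm_len - mature_len - 10L), 1)
  }
  arm <- paste(sample(c("A", "C", "G", "T"), arm_len, replace = TRUE),
               collapse = "")
  # U-biased mature start
  mature <- .random_mature(mature_len, avoid = avoid)
  substr(arm, mature_offset + 1L, mature_offset + mature_len) <- mature
  loop <- paste(sample(c("A", "C"), loop_len, replace = TRUE),
                collapse = "")
  arm2 <- revcomp(arm)
  if (n_noise > 0) {
    pos <- sample.int(nchar(arm2), n_noise)
    for (p in pos) {
      substr(arm2, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                           substr(arm2, p, p)), 1)
    }
  }
  if (mature_arm == "5p") {
    precursor <- paste0(arm, loop, arm2)
    m_off <- mature_offset
  } else {
    precursor <- paste0(arm2, loop, arm)
    m_off <- nchar(arm2) + loop_len + mature_offset
  }
  mature <- substr(precursor, m_off + 1L, m_off + mature_len)
  list(precursor = precursor, mature = mature, mature_offset = m_off,
       mature_arm = mature_arm)
}

#' Generate a synthetic genome with planted miRNA loci and annotation
#'
#' Background chromosomes are uniform-random; gene models (exons and
#' introns), repeat intervals, known mature miRNA loci, novel precursor
#' hairpins and genomic clusters are planted into non-overlapping
#' positions, overwriting the background. All planted coordinates are
#' recorded as ground truth. Deterministic under the config seed.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (named character vector), `truth` (list:
#'   `mirna_loci` data.frame, `mature_sequences`, `novel_precursors`,
#'   `true_clusters`, `true_de`, `baseline`), `annotation` (list of
#'   `GRanges`: `exons`, `introns`, `repeats`), `ncrna` (named character
#'   vector of decoy ncRNAs), and `known_ref` (named character vector,
#'   miRBase-style known mature reference).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_chrom <- config$n_chromosomes
  clen <- config$chromosome_length
  chroms <- vapply(seq_len(n_chrom), function(i)
    paste(sample(c("A", "C", "G", "T"), clen, replace = TRUE),
          collapse = ""), character(1))
  names(chroms) <- sprintf("chr%d", seq_len(n_chrom))
  occ <- new.env()
  occ$tab <- data.frame(chrom = integer(0), start = integer(0),
                        end = integer(0))

  plant <- function(seqs, at) {
    # overwrite background at recorded position (forward-strand string)
    substr(chroms[[at["chrom"]]], at["start"], at["end"]) <<- seqs
  }

  # --- gene models -------------------------------------------------------
  exons <- list(); introns <- list()
  for (g in seq_len(config$n_genes)) {
    n_ex <- sample(2:4, 1)
    ex_len <- sample(150:400, n_ex, replace = TRUE)
    in_len <- sample(100:300, n_ex - 1, replace = TRUE)
    g_len <- sum(ex_len) + sum(in_len)
    at <- .place(occ, clen, n_chrom, g_len)
    strand <- sample(c("+", "-"), 1)
    pos <- at["start"]
    for (i in seq_len(n_ex)) {
      exons[[length(exons) + 1L]] <- data.frame(
        chrom = names(chroms)[at["chrom"]], start = pos,
        end = pos + ex_len[i] - 1L, strand = strand, gene = g)
      pos <- pos + ex_len[i]
      if (i < n_ex) {
        introns[[length(introns) + 1L]] <- data.frame(
          chrom = names(chroms)[at["chrom"]], start = pos,
          end = pos + in_len[i] - 1L, strand = strand, gene = g)
        pos <- pos + in_len[i]
      }
    }
  }
  to_gr <- function(lst) {
    if (length(lst) == 0) return(GenomicRanges::GRanges())
    df <- do.call(rbind, lst)
    GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                           strand = df$strand, gene = df$gene)
  }
  gr_exons <- to_gr(exons); gr_introns <- to_gr(introns)

  # --- repeats -----------------------------------------------------------
  reps <- list()
  for (r in seq_len(config$n_repeats)) {
    len <- sample(200:800, 1)
    at <- .place(occ, clen, n_chrom, len)
    reps[[length(reps) + 1L]] <- data.frame(
      chrom = names(chroms)[at["chrom"]], start = at["start"],
      end = at["end"], strand = "+", gene = NA_integer_)
  }
  gr_reps <- to_gr(reps)

  # --- known mature miRNAs ----------------------------------------------
  lens <- sample(as.integer(names(.mature_length_probs)),
                 config$n_known_mirnas, replace = TRUE,
                 prob = .mature_length_probs)
  # miRBase-style names: a handful of families get two members
  fam_ids <- sample(100:999, config$n_known_mirnas - 2)
  known_names <- c(paste0("pyr-miR", fam_ids,
                          sample(c("a", "c"), length(fam_ids),
                                 replace = TRUE)),
                   paste0("pyr-miR", fam_ids[1], "b"),
                   paste0("pyr-miR", fam_ids[2], "b"))
  seed6 <- substr(.as_dna(config$adapter_3p), 1, 6)
  known_seq <- vapply(lens, .random_mature, character(1), avoid = seed6)
  names(known_seq) <- known_names
  mirna_loci <- list()
  for (i in seq_along(known_seq)) {
    at <- .place(occ, clen, n_chrom, nchar(known_seq[i]))
    strand <- sample(c("+", "-"), 1)
    plant(if (strand == "+") known_seq[[i]] else revcomp(known_seq[[i]]), at)
    mirna_loci[[length(mirna_loci) + 1L]] <- data.frame(
      name = known_names[i], chrom = names(chroms)[at["chrom"]],
      start = at["start"], end = at["end"], strand = strand,
      source = "known", stringsAsFactors = FALSE)
  }

  # --- novel precursors --------------------------------------------------
  novel_prec <- list()
  for (i in seq_len(config$n_novel_precursors)) {
    hp <- .build_precursor(mature_arm = sample(c("5p", "3p"), 1),
                           avoid = seed6)
    at <- .place(occ, clen, n_chrom, nchar(hp$precursor), buffer = 500L)
    strand <- sample(c("+", "-"), 1)
    plant(if (strand == "+") hp$precursor else revcomp(hp$precursor), at)
    nm <- sprintf("sim-novel-%03d", i)
    if (strand == "+") {
      m_start <- at["start"] + hp$mature_offset
    } else {
      m_start <- at["end"] - hp$mature_offset - nchar(hp$mature) + 1L
    }
    mirna_loci[[length(mirna_loci) + 1L]] <- data.frame(
      name = nm, chrom = names(chroms)[at["chrom"]],
      start = unname(m_start), end = unname(m_start + nchar(hp$mature) - 1L),
      strand = strand, source = "novel", stringsAsFactors = FALSE)
    novel_prec[[length(novel_prec) + 1L]] <- data.frame(
      name = nm, mature = hp$mature, precursor = hp$precursor,
      mature_arm = hp$mature_arm, chrom = names(chroms)[at["chrom"]],
      prec_start = unname(at["start"]), prec_end = unname(at["end"]),
      strand = strand, stringsAsFactors = FALSE)
  }
  novel_prec <- do.call(rbind, novel_prec)

  # --- planted clusters: extra copies of known matures -------------------
  true_clusters <- list()
  if (config$n_planted_clusters > 0) {
    for (cl in seq_len(config$n_planted_clusters)) {
      members <- sample(names(known_seq), 2)
      gap <- sample(1000:max(1001L, config$cluster_span - 1000L), 1)
      len1 <- nchar(known_seq[[members[1]]])
      len2 <- nchar(known_seq[[members[2]]])
      span <- len1 + gap + len2
      at <- .place(occ, clen, n_chrom, span, buffer = 600L)
      s1 <- at["start"]; e1 <- s1 + len1 - 1L
      s2 <- e1 + gap + 1L; e2 <- s2 + len2 - 1L
      for (k in 1:2) {
        s <- if (k == 1) s1 else s2; e <- if (k == 1) e1 else e2
        strand <- sample(c("+", "-"), 1)
        sq <- known_seq[[members[k]]]
        plant(if (strand == "+") sq else revcomp(sq),
              c(chrom = unname(at["chrom"]), start = unname(s),
                end = unname(e)))
        mirna_loci[[length(mirna_loci) + 1L]] <- data.frame(
          name = members[k], chrom = names(chroms)[at["chrom"]],
          start = unname(s), end = unname(e), strand = strand,
          source = "known_cluster_copy", stringsAsFactors = FALSE)
      }
      true_clusters[[cl]] <- list(chrom = names(chroms)[at["chrom"]],
                                  members = members,
                                  starts = c(unname(s1), unname(s2)))
    }
  }
  mirna_loci <- do.call(rbind, mirna_loci)
  rownames(mirna_loci) <- NULL

  # --- ncRNA decoys (not genome-derived) ---------------------------------
  ncrna <- vapply(seq_len(config$n_ncrna), function(i)
    paste(sample(c("A", "C", "G", "T"), sample(80:160, 1),
                 replace = TRUE), collapse = ""), character(1))
  names(ncrna) <- sprintf("sim-ncRNA-%02d", seq_along(ncrna))

  # --- abundance baselines and planted DE trends -------------------------
  all_names <- c(names(known_seq), novel_prec$name)
  baseline <- stats::rlnorm(length(all_names), meanlog = log(60), sdlog = 1)
  baseline <- pmax(baseline, 15)
  names(baseline) <- all_names
  true_de <- setNames(rep("flat", length(all_names)), all_names)
  de_pool <- sample(names(known_seq),
                    min(config$n_de_up + config$n_de_down,
                        length(known_seq)))
  if (config$n_de_up > 0) {
    true_de[de_pool[seq_len(config$n_de_up)]] <- "up"
  }
  if (config$n_de_down > 0) {
    true_de[de_pool[config$n_de_up + seq_len(config$n_de_down)]] <- "down"
  }

  mature_sequences <- c(known_seq,
                        setNames(novel_prec$mature, novel_prec$name))
  list(genome = chroms,
       truth = list(mirna_loci = mirna_loci,
                    mature_sequences = mature_sequences,
                    novel_precursors = novel_prec,
                    true_clusters = true_clusters,
                    true_de = true_de,
                    baseline = baseline),
       annotation = list(exons = gr_exons, introns = gr_introns,
                         repeats = gr_reps),
       ncrna = ncrna,
       known_ref = known_seq)
}

# Stage profile for one miRNA: geometric ramp over n stages reaching
# `fold` (up) or 1/fold (down); flat otherwise.
.stage_profile <- function(trend, n_stages, fold) {
  switch(trend,
         up = fold^(seq(0, 1, length.out = n_stages)),
         down = fold^(seq(1, 0, length.out = n_stages)),
         rep(1, n_stages))
}

#' Simulate staged small-RNA sequencing libraries
#'
#' Per stage, planted miRNA read counts are negative binomial around
#' means proportional to `baseline * stage profile`; contaminant reads
#' are drawn from ncRNA decoys, repeat/exon/intron/intergenic genome
#' fragments, poly-A reads and sub-18-nt fragments. Every read is the
#' insert plus the 3' adapter, padded with A / truncated to the read
#' length, with constant high base qualities (optionally degraded for a
#' configured fraction). Deterministic under `config$seed + 1`.
#'
#' @param genome named character vector from [generate_genome()].
#' @param truth,annotation,ncrna companion outputs of [generate_genome()].
#' @param config the [sim_config()].
#' @return list with `libraries` (named list of data.frames `id`,
#'   `sequence`, `quality`), `truth_counts` (matrix: planted miRNA x
#'   stage drawn counts), and `read_classes` (per-stage tallies of read
#'   classes incl. expected cleaning survivors).
#' @export
simulate_libraries <- function(genome, truth, annotation, ncrna, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  stages <- config$stage_labels
  n_stages <- length(stages)
  mature <- truth$mature_sequences
  baseline <- truth$baseline[names(mature)]
  profiles <- vapply(names(mature), function(nm)
    .stage_profile(truth$true_de[[nm]], n_stages, config$de_fold),
    numeric(n_stages))  # stages x mirnas
  mix <- c(ncrna = 0.25, repeat_frag = 0.30, exon = 0.08, intron = 0.10,
           intergenic = 0.15, polyA = 0.05, short = 0.07)
  seed6 <- substr(.as_dna(config$adapter_3p), 1, 6)

  frag_from <- function(gr, sense) {
    # a read fragment from a random annotated interval; `sense` reads map
    # on the feature strand
    .sample_clean(function() {
      i <- sample.int(length(gr), 1)
      w <- min(.frag_len(),
               BiocGenerics::width(gr)[i])
      s <- BiocGenerics::start(gr)[i] +
        sample.int(BiocGenerics::width(gr)[i] - w + 1L, 1) - 1L
      chrom <- as.character(GenomicRanges::seqnames(gr))[i]
      fwd <- substr(genome[[chrom]], s, s + w - 1L)
      feat_strand <- as.character(GenomicRanges::strand(gr))[i]
      read_strand <- if (sense) feat_strand else setdiff(c("+", "-"),
                                                         feat_strand)
      if (read_strand == "+") fwd else .rc(fwd)
    }, seed6)
  }

  truth_counts <- matrix(0L, nrow = length(mature), ncol = n_stages,
                         dimnames = list(names(mature), stages))
  libraries <- list()
  read_classes <- list()
  n_planted_total <- round(config$reads_per_library *
                             (1 - config$contaminant_fraction))
  n_cont <- config$reads_per_library - n_planted_total
  for (j in seq_len(n_stages)) {
    mu <- baseline * profiles[j, ]
    mu <- mu / sum(mu) * n_planted_total
    counts <- rnbinom(length(mu), mu = mu, size = config$nb_dispersion)
    truth_counts[, j] <- counts
    inserts <- rep(unname(mature), counts)
    classes <- rep("mirna", length(inserts))

    cont_n <- round(n_cont * mix)
    cont <- character(0); ccls <- character(0)
    if (cont_n[["ncrna"]] > 0) {
      cs <- vapply(seq_len(cont_n[["ncrna"]]), function(k)
        .sample_clean(function() {
          src <- ncrna[[sample.int(length(ncrna), 1)]]
          w <- .frag_len()
          s <- sample.int(nchar(src) - w + 1L, 1)
          substr(src, s, s + w - 1L)
        }, seed6), character(1))
      cont <- c(cont, cs); ccls <- c(ccls, rep("ncrna", length(cs)))
    }
    for (cls in c("repeat_frag", "exon", "intron")) {
      gr <- switch(cls, repeat_frag = annotation$repeats,
                   exon = annotation$exons, intron = annotation$introns)
      if (cont_n[[cls]] > 0 && length(gr) > 0) {
        cs <- vapply(seq_len(cont_n[[cls]]), function(k)
          frag_from(gr, sense = runif(1) < 0.5), character(1))
        cont <- c(cont, cs); ccls <- c(ccls, rep(cls, length(cs)))
      }
    }
    if (cont_n[["intergenic"]] > 0) {
      cs <- vapply(seq_len(cont_n[["intergenic"]]), function(k)
        .sample_clean(function() {
          chrom <- sample(names(genome), 1)
          w <- .frag_len()
          s <- sample.int(nchar(genome[[chrom]]) - w + 1L, 1)
          frag <- substr(genome[[chrom]], s, s + w - 1L)
          if (runif(1) < 0.5) frag else .rc(frag)
        }, seed6), character(1))
      cont <- c(cont, cs); ccls <- c(ccls, rep("intergenic", length(cs)))
    }
    if (cont_n[["polyA"]] > 0) {
      cs <- strrep("A", .frag_len(cont_n[["polyA"]]))
      cont <- c(cont, cs); ccls <- c(ccls, rep("polyA", length(cs)))
    }
    if (cont_n[["short"]] > 0) {
      cs <- vapply(seq_len(cont_n[["short"]]), function(k) {
        chrom <- sample(names(genome), 1)
        w <- sample(10:16, 1)
        s <- sample.int(nchar(genome[[chrom]]) - w + 1L, 1)
        substr(genome[[chrom]], s, s + w - 1L)
      }, character(1))
      cont <- c(cont, cs); ccls <- c(ccls, rep("short", length(cs)))
    }
    inserts <- c(inserts, cont)
    classes <- c(classes, ccls)

    # raw read: insert + adapter, padded with A / truncated to read length
    raw <- paste0(inserts, config$adapter_3p)
    raw <- substr(raw, 1L, config$read_length)
    pad <- config$read_length - nchar(raw)
    raw <- paste0(raw, strrep("A", pmax(pad, 0L)))
    qual <- strrep(rawToChar(as.raw(33L + 40L)), config$read_length)
    quals <- rep(qual, length(raw))
    degraded <- rep(FALSE, length(raw))
    if (config$degraded_quality_fraction > 0) {
      bad <- runif(length(raw)) < config$degraded_quality_fraction
      quals[bad] <- strrep(rawToChar(as.raw(33L + 2L)), config$read_length)
      degraded[bad] <- TRUE
    }
    ord <- sample.int(length(raw))
    libraries[[stages[j]]] <- data.frame(
      id = sprintf("%s_read%06d", stages[j], seq_along(raw)),
      sequence = raw[ord], quality = quals[ord], stringsAsFactors = FALSE)
    # expected cleaning survivors: inserts of length 18-30, not >= 80% A,
    # not degraded
    n_a <- nchar(inserts) - nchar(gsub("A", "", inserts, fixed = TRUE))
    survives <- nchar(inserts) >= 18 & nchar(inserts) <= 30 &
      n_a / nchar(inserts) < 0.8 & !degraded[seq_along(inserts)]
    read_classes[[stages[j]]] <- data.frame(
      class = names(table(classes)),
      n = as.integer(table(classes)),
      survivors = as.integer(tapply(survives, classes, sum)[
        names(table(classes))]),
      stringsAsFactors = FALSE)
  }
  list(libraries = libraries, truth_counts = truth_counts,
       read_classes = read_classes)
}

#' Generate transcripts with planted miRNA target sites
#'
#' Each planted site is the reverse complement of a mature miRNA with a
#' controlled edit set (G:U wobbles and/or full mismatches at chosen
#' miRNA positions) embedded at a recorded transcript offset. Whether
#' the planted site complies with the five target-prediction rules is
#' computed from the edit set and recorded; requesting a compliance flag
#' that contradicts the edit set is an error. Deterministic under
#' `config$seed + 2`.
#'
#' @param truth truth list from [generate_genome()].
#' @param config the [sim_config()].
#' @param site_specs optional data.frame with columns `mirna`,
#'   `wobble_at`, `mismatch_at` (comma-separated miRNA positions, "" for
#'   none) and optionally `compliant` (validated against the edit set);
#'   when NULL, `n_planted_targets` random sites are planted (a mix of
#'   perfect, wobbled, and rule-violating).
#' @return list with `transcripts` (named character vector) and
#'   `registry` (data.frame: `mirna`, `transcript`, `position`,
#'   `wobble_at`, `mismatch_at`, `compliant`).
#' @export
generate_transcripts <- function(truth, config, site_specs = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  mature <- truth$mature_sequences
  tx_len <- sample(400:1200, config$n_transcripts, replace = TRUE)
  transcripts <- vapply(tx_len, function(l)
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""),
    character(1))
  names(transcripts) <- sprintf("tx%03d", seq_along(transcripts))

  parse_pos <- function(x) {
    if (is.na(x) || x == "") integer(0) else
      as.integer(strsplit(x, ",", fixed = TRUE)[[1]])
  }
  if (is.null(site_specs)) {
    n <- config$n_planted_targets
    site_specs <- data.frame(mirna = sample(names(mature), n, replace = TRUE),
                             wobble_at = "", mismatch_at = "",
                             stringsAsFactors = FALSE)
    kind <- sample(c("perfect", "wobble", "mismatch_ok", "violating"), n,
                   replace = TRUE, prob = c(0.3, 0.25, 0.2, 0.25))
    for (i in seq_len(n)) {
      m <- strsplit(.as_dna(mature[[site_specs$mirna[i]]]), "")[[1]]
      wobblable <- which(m %in% c("G", "T"))
      L <- length(m)
      if (kind[i] == "wobble" && length(wobblable) > 0) {
        site_specs$wobble_at[i] <- paste(
          sample(wobblable, min(2, length(wobblable))), collapse = ",")
      } else if (kind[i] == "mismatch_ok") {
        # one full mismatch outside positions 10-11, plus room under the
        # positional sums
        ok_pos <- setdiff(seq_len(L), 10:11)
        site_specs$mismatch_at[i] <- as.character(sample(ok_pos, 1))
      } else if (kind[i] == "violating") {
        site_specs$mismatch_at[i] <- as.character(sample(10:11, 1))
      }
    }
  }
  registry <- list()
  for (i in seq_len(nrow(site_specs))) {
    mi <- site_specs$mirna[i]
    mseq <- .as_dna(mature[[mi]])
    m <- strsplit(mseq, "")[[1]]
    L <- length(m)
    site <- strsplit(revcomp(mseq), "")[[1]]  # site[L - p + 1] faces pos p
    wob <- parse_pos(site_specs$wobble_at[i])
    mis <- parse_pos(site_specs$mismatch_at[i])
    status <- rep("match", L)
    for (p in wob) {
      if (!m[p] %in% c("G", "T")) {
        stop(sprintf("position %d of %s cannot form a G:U wobble", p, mi),
             call. = FALSE)
      }
      site[L - p + 1L] <- if (m[p] == "G") "T" else "G"
      status[p] <- "GU"
    }
    for (p in mis) {
      site[L - p + 1L] <- m[p]  # self-pairing base: always a mismatch
      status[p] <- "mismatch"
    }
    w <- ifelse(status == "mismatch", 1, ifelse(status == "GU", 0.5, 0))
    compliant <- as.logical(rule_kernel(matrix(w, nrow = 1)))
    if (!is.null(site_specs$compliant) && !is.na(site_specs$compliant[i]) &&
        site_specs$compliant[i] != compliant) {
      stop(sprintf("edit set for %s contradicts requested compliance", mi),
           call. = FALSE)
    }
    # choose a slot that does not overlap a previously planted site
    repeat {
      tx <- sample(names(transcripts), 1)
      pos <- sample.int(nchar(transcripts[[tx]]) - L + 1L, 1)
      planted <- Filter(function(r) r$transcript == tx, registry)
      if (!any(vapply(planted, function(r)
        pos <= r$position + nchar(mature[[r$mirna]]) - 1L &&
          r$position <= pos + L - 1L, logical(1)))) break
    }
    site_str <- paste(site, collapse = "")
    substr(transcripts[[tx]], pos, pos + L - 1L) <- site_str
    registry[[length(registry) + 1L]] <- data.frame(
      mirna = mi, transcript = tx, position = pos,
      wobble_at = site_specs$wobble_at[i],
      mismatch_at = site_specs$mismatch_at[i],
      compliant = compliant, stringsAsFactors = FALSE)
  }
  registry <- do.call(rbind, registry)
  list(transcripts = transcripts, registry = registry)
}

#' Run the full synthetic study generator
#'
#' Convenience wrapper: [generate_genome()], [simulate_libraries()] and
#' [generate_transcripts()] under one config.
#'
#' @param config a [sim_config()].
#' @return list combining all generator outputs: `genome`, `truth`,
#'   `annotation`, `ncrna`, `known_ref`, `libraries`, `truth_counts`,
#'   `read_classes`, `transcripts`, `target_registry`.
#' @export
simulate_srna_study <- function(config = sim_config()) {
  g <- generate_genome(config)
  libs <- simulate_libraries(g$genome, g$truth, g$annotation, g$ncrna,
                             config)
  tx <- generate_transcripts(g$truth, config)
  c(g, libs, list(transcripts = tx$transcripts,
                  target_registry = tx$registry))
}

#' Write generator outputs to standard file formats
#'
#' Writes `genome.fa`, `annotation.gff3` (1-based inclusive),
#' `ncrna.fa`, `known_mirnas.fa` (headers "name family"),
#' `transcripts.fa`, one `lib_<stage>.fastq` per library, and truth
#' tables under `truth/`.
#'
#' @param sim output of [simulate_srna_study()].
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_simdata <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "truth"), showWarnings = FALSE)
  wfa <- function(x, path) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), path)
  }
  wfa(sim$genome, file.path(outdir, "genome.fa"))
  wfa(sim$ncrna, file.path(outdir, "ncrna.fa"))
  known <- sim$known_ref
  names(known) <- paste(names(known), mirna_family(names(known)))
  wfa(known, file.path(outdir, "known_mirnas.fa"))
  wfa(sim$transcripts, file.path(outdir, "transcripts.fa"))
  gff <- list()
  for (kind in c("exons", "introns", "repeats")) {
    gr <- sim$annotation[[kind]]
    if (length(gr) == 0) next
    type <- sub("s$", "", kind)
    gff[[kind]] <- sprintf(
      "%s\tmirfruit_sim\t%s\t%d\t%d\t.\t%s\t.\tID=%s_%d",
      as.character(GenomicRanges::seqnames(gr)), type,
      BiocGenerics::start(gr), BiocGenerics::end(gr),
      as.character(GenomicRanges::strand(gr)), type,
      seq_along(gr))
  }
  writeLines(c("##gff-version 3", unlist(gff)),
             file.path(outdir, "annotation.gff3"))
  for (st in names(sim$libraries)) {
    write_fastq(sim$libraries[[st]],
                file.path(outdir, sprintf("lib_%s.fastq", st)))
  }
  write.table(sim$truth$mirna_loci,
              file.path(outdir, "truth", "mirna_loci.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(name = rownames(sim$truth_counts),
                         sim$truth_counts, check.names = FALSE),
              file.path(outdir, "truth", "counts.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$target_registry,
              file.path(outdir, "truth", "targets.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outdir)
}
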