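# Raw-read cleaning, collapsing to unique sequences, annotation-driven
# categorization and the per-library summary statistics.

#' Read a FASTQ file into a sequence/quality data.frame
#'
#' @param path FASTQ file path (uncompressed or gzip).
#' @return data.frame with columns `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  n <- length(lines)
  if (n %% 4 != 0) {
    stop(sprintf("malformed FASTQ: %d lines is not a multiple of 4", n),
         call. = FALSE)
  }
  ids <- lines[seq(1, n, by = 4)]
  seqs <- lines[seq(2, n, by = 4)]
  plus <- lines[seq(3, n, by = 4)]
  quals <- lines[seq(4, n, by = 4)]
  bad_id <- which(!startsWith(ids, "@"))
  if (length(bad_id) > 0) {
    stop(sprintf("malformed FASTQ record at line %d: header must start with @",
                 (bad_id[1] - 1) * 4 + 1), call. = FALSE)
  }
  bad_plus <- which(!startsWith(plus, "+"))
  if (length(bad_plus) > 0) {
    stop(sprintf("malformed FASTQ record at line %d: separator must start with +",
                 (bad_plus[1] - 1) * 4 + 3), call. = FALSE)
  }
  bad_len <- which(nchar(seqs) != nchar(quals))
  if (length(bad_len) > 0) {
    stop(sprintf("malformed FASTQ record at line %d: sequence/quality length mismatch",
                 (bad_len[1] - 1) * 4 + 2), call. = FALSE)
  }
  data.frame(id = sub("^@", "", ids), sequence = seqs, quality = quals,
             stringsAsFactors = FALSE)
}

#' Write a sequence/quality data.frame as FASTQ
#'
#' @param reads data.frame with columns `sequence` and `quality` (and
#'   optionally `id`).
#' @param path output file path.
#' @export
write_fastq <- function(reads, path) {
  ids <- if ("id" %in% names(reads)) reads$id else
    sprintf("read_%d", seq_len(nrow(reads)))
  out <- character(4 * nrow(reads))
  out[seq(1, length(out), by = 4)] <- paste0("@", ids)
  out[seq(2, length(out), by = 4)] <- reads$sequence
  out[seq(3, length(out), by = 4)] <- "+"
  out[seq(4, length(out), by = 4)] <- reads$quality
  writeLines(out, path)
  invisible(path)
}

# Locate the 3' adapter in each read: leftmost position where a prefix of
# the adapter (>= min_overlap nt, or the full remaining read) matches
# exactly. Returns the 1-based start of the adapter, or NA when absent.
.find_adapter <- function(seqs, adapter, min_overlap = 6L) {
  seed <- substr(adapter, 1, min_overlap)
  pos <- rep(NA_integer_, length(seqs))
  cand <- regexpr(seed, seqs, fixed = TRUE)
  todo <- seq_along(seqs)
  while (length(todo) > 0) {
    hit <- todo[cand[todo] > 0]
    if (length(hit) == 0) break
    p <- as.integer(cand[hit])
    # verify the adapter prefix extends to the read end (or full adapter)
    ov <- pmin(nchar(adapter), nchar(seqs[hit]) - p + 1L)
    ok <- substring(seqs[hit], p, p + ov - 1L) == substring(adapter, 1L, ov)
    pos[hit[ok]] <- p[ok]
    # retry seeds that failed full verification, further right
    retry <- hit[!ok]
    if (length(retry) > 0) {
      nxt <- vapply(retry, function(i) {
        s <- seqs[i]
        from <- as.integer(cand[i]) + 1L
        repeat {
          q <- regexpr(seed, substr(s, from, nchar(s)), fixed = TRUE)
          if (q < 0) return(NA_integer_)
          p2 <- from + as.integer(q) - 1L
          ov2 <- min(nchar(adapter), nchar(s) - p2 + 1L)
          if (ov2 >= 6L &&
              substr(s, p2, p2 + ov2 - 1L) == substr(adapter, 1, ov2)) {
            return(p2)
          }
          from <- p2 + 1L
        }
      }, integer(1))
      pos[retry] <- nxt
    }
    break
  }
  pos
}

#' Clean a raw small-RNA library
#'
#' Applies, in order: 3' adapter removal (leftmost exact match of an
#' adapter prefix with at least `min_overlap` nt of overlap; reads without
#' a located adapter keep their full length and are usually removed by the
#' length filter), poly-A removal (trimmed inserts that are >= 80% A),
#' a mean-quality filter, and the length window filter. Survivors are
#' collapsed to unique sequences with read counts.
#'
#' @param reads FASTQ file path or a data.frame with columns `sequence`
#'   and `quality`.
#' @param adapter_3p 3' adapter sequence (non-empty).
#' @param min_len,max_len insert length window (defaults 18 and 30 nt).
#' @param quality_threshold minimum mean Phred quality (default 20;
#'   Phred+33 encoding).
#' @param min_overlap minimum adapter prefix overlap (default 6 nt).
#' @param library_id optional stage label stored on the result.
#' @return object of class `clean_read_set`: list with `library_id`,
#'   `records` (data.frame `sequence`, `count`, sorted by decreasing
#'   count), `total_raw` and `total_clean`.
#' @export
clean_reads <- function(reads, adapter_3p, min_len = 18L, max_len = 30L,
                        quality_threshold = 20, min_overlap = 6L,
                        library_id = NA_character_) {
  stopifnot(is.character(adapter_3p), nchar(adapter_3p) >= min_overlap)
  if (is.character(reads) && length(reads) == 1) reads <- read_fastq(reads)
  stopifnot(all(c("sequence", "quality") %in% names(reads)))
  seqs <- .as_dna(reads$sequence)
  total_raw <- length(seqs)

  pos <- .find_adapter(seqs, .as_dna(adapter_3p), min_overlap)
  ins_end <- ifelse(is.na(pos), nchar(seqs), pos - 1L)
  insert <- substr(seqs, 1L, ins_end)
  qual <- substr(reads$quality, 1L, ins_end)

  keep <- nchar(insert) > 0
  # poly-A: trimmed insert at least 80% A
  n_a <- nchar(insert) - nchar(gsub("A", "", insert, fixed = TRUE))
  keep <- keep & (n_a / pmax(nchar(insert), 1L) < 0.8)
  # quality: mean Phred over the insert
  mean_q <- vapply(qual, function(q) {
    if (nchar(q) == 0) return(0)
    mean(utf8ToInt(q) - 33L)
  }, numeric(1), USE.NAMES = FALSE)
  keep <- keep & (mean_q >= quality_threshold)
  # length window
  keep <- keep & nchar(insert) >= min_len & nchar(insert) <= max_len

  surv <- insert[keep]
  tab <- sort(table(surv), decreasing = TRUE)
  records <- data.frame(sequence = names(tab), count = as.integer(tab),
                        stringsAsFactors = FALSE)
  structure(list(library_id = library_id, records = records,
                 total_raw = total_raw, total_clean = sum(records$count)),
            class = "clean_read_set")
}

#' @export
print.clean_read_set <- function(x, ...) {
  cat(sprintf("clean_read_set [%s]: %d clean / %d raw reads, %d unique sequences\n",
              x$library_id, x$total_clean, x$total_raw, nrow(x$records)))
  invisible(x)
}

# Map a set of variable-width sequences to the genome with PDict grouped
# by width; returns a data.frame (seq_index, chrom, start, end, strand).
.map_many <- function(genome, seqs) {
  genome <- .as_genome(genome)
  hits <- list()
  widths <- nchar(seqs)
  for (w in unique(widths)) {
    idx <- which(widths == w)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(seqs[idx]))
    pd_rc <- Biostrings::PDict(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[idx])))
    for (chrom in names(genome)) {
      for (strand in c("+", "-")) {
        m <- Biostrings::matchPDict(if (strand == "+") pd else pd_rc,
                                    genome[[chrom]])
        counts <- S4Vectors::elementNROWS(m)
        if (sum(counts) == 0) next
        um <- unlist(m)
        hits[[length(hits) + 1L]] <- data.frame(
          seq_index = idx[rep(seq_along(counts), counts)],
          chrom = chrom,
          start = BiocGenerics::start(um),
          end = BiocGenerics::end(um),
          strand = strand, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(seq_index = integer(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, hits)
}

#' Categorize clean reads against annotations
#'
#' Assigns every unique clean sequence to exactly one category by fixed
#' priority: ncRNA (rRNA/snRNA/snoRNA/tRNA) > known miRNA > repeat >
#' exon_sense > exon_antisense > intron_sense > intron_antisense >
#' unannotated. ncRNA and known-miRNA matching is exact sequence search
#' (a read matches an ncRNA reference when it is a substring of it);
#' repeat/exon/intron assignment requires an exact genome mapping that
#' overlaps the corresponding annotation interval.
#'
#' @param clean a `clean_read_set`.
#' @param ncrna ncRNA reference (`DNAStringSet` or character vector).
#' @param genome genome (`DNAStringSet` or named character vector).
#' @param annotation list of `GRanges`: `exons`, `introns`, `repeats`
#'   (any may be empty).
#' @param known_mirnas known mature miRNA reference (named character
#'   vector or `DNAStringSet`; T/U equivalent).
#' @return object of class `library_stats`: list with `library_id`,
#'   `categories` (named counts over the eight categories), `clean_reads`,
#'   `total_reads`, and `category_of` (per-unique-sequence assignment).
#' @export
categorize <- function(clean, ncrna, genome, annotation, known_mirnas) {
  stopifnot(inherits(clean, "clean_read_set"))
  for (nm in c("exons", "introns", "repeats")) {
    if (is.null(annotation[[nm]])) {
      stop("annotation must provide element: ", nm, call. = FALSE)
    }
  }
  seqs <- clean$records$sequence
  counts <- clean$records$count
  cat_of <- rep("unannotated", length(seqs))

  # genome mapping for repeat/exon/intron assignment
  hits <- .map_many(genome, seqs)
  if (nrow(hits) > 0) {
    gr <- GenomicRanges::GRanges(hits$chrom,
                                 IRanges::IRanges(hits$start, hits$end),
                                 strand = hits$strand)
    assign_overlap <- function(target, same_strand) {
      if (length(target) == 0) return(integer(0))
      ov <- GenomicRanges::findOverlaps(gr, target, type = "within",
                                        ignore.strand = TRUE)
      qh <- S4Vectors::queryHits(ov)
      if (length(qh) == 0) return(integer(0))
      same <- as.character(GenomicRanges::strand(gr))[qh] ==
        as.character(GenomicRanges::strand(target))[S4Vectors::subjectHits(ov)]
      unique(hits$seq_index[qh[same == same_strand]])
    }
    idx_repeat <- {
      ov <- GenomicRanges::findOverlaps(gr, annotation$repeats,
                                        type = "within",
                                        ignore.strand = TRUE)
      unique(hits$seq_index[S4Vectors::queryHits(ov)])
    }
    idx_exon_s <- assign_overlap(annotation$exons, TRUE)
    idx_exon_a <- assign_overlap(annotation$exons, FALSE)
    idx_intron_s <- assign_overlap(annotation$introns, TRUE)
    idx_intron_a <- assign_overlap(annotation$introns, FALSE)
    # lowest priority first, later assignments overwrite
    cat_of[idx_intron_a] <- "intron_antisense"
    cat_of[idx_intron_s] <- "intron_sense"
    cat_of[idx_exon_a] <- "exon_antisense"
    cat_of[idx_exon_s] <- "exon_sense"
    cat_of[idx_repeat] <- "repeat"
  }

  # known miRNA: exact equality (T/U equivalent)
  known <- unique(.as_dna(as.character(known_mirnas)))
  cat_of[seqs %in% known] <- "known_mirna"

  # ncRNA: exact equality or substring of a reference entry
  nc <- .as_dna(as.character(ncrna))
  if (length(nc) > 0) {
    is_nc <- seqs %in% nc
    maybe <- which(!is_nc)
    if (length(maybe) > 0) {
      nc_cat <- paste(nc, collapse = "|")
      is_nc[maybe] <- vapply(seqs[maybe], function(s)
        grepl(s, nc_cat, fixed = TRUE), logical(1), USE.NAMES = FALSE)
    }
    cat_of[is_nc] <- "rrna_etc"
  }

  lev <- c("exon_antisense", "exon_sense", "intron_antisense",
           "intron_sense", "known_mirna", "rrna_etc", "repeat",
           "unannotated")
  categories <- vapply(lev, function(l) sum(counts[cat_of == l]),
                       numeric(1))
  structure(list(library_id = clean$library_id,
                 categories = categories,
                 clean_reads = clean$total_clean,
                 total_reads = clean$total_raw,
                 category_of = setNames(cat_of, seqs)),
            class = "library_stats")
}

#' Aggregate per-library categorization statistics
#'
#' Per-category arithmetic means are rounded half-up to integers (the
#' convention that turns x.5 into x+1). The pooled clean-read percentage
#' is `100 * sum(clean) / sum(total)` and the average ncRNA share is
#' `100 * mean(rrna_etc) / mean(clean)`, both to 2 decimals.
#'
#' @param stats list of `library_stats` objects (length >= 1), or a
#'   data.frame/matrix of per-library category counts with rows
#'   `total_reads`, `clean_reads` and the eight categories.
#' @return list with `table` (categories x libraries matrix plus an
#'   `Average` column), `pooled_clean_pct`, and `avg_ncrna_share_pct`.
#' @export
aggregate_stats <- function(stats) {
  if (is.list(stats) && all(vapply(stats, inherits, logical(1),
                                   "library_stats"))) {
    mat <- vapply(stats, function(s) {
      c(total_reads = s$total_reads, clean_reads = s$clean_reads,
        s$categories)
    }, numeric(10))
    colnames(mat) <- vapply(stats, function(s) as.character(s$library_id),
                            character(1))
  } else {
    mat <- as.matrix(stats)
  }
  stopifnot(all(c("total_reads", "clean_reads") %in% rownames(mat)))
  avg <- round_half_up(rowMeans(mat))
  table <- cbind(mat, Average = avg)
  list(
    table = table,
    pooled_clean_pct = round_half_up(
      100 * sum(mat["clean_reads", ]) / sum(mat["total_reads", ]), 2),
    avg_ncrna_share_pct = if ("rrna_etc" %in% rownames(mat)) {
      round_half_up(100 * mean(mat["rrna_etc", ]) /
                      mean(mat["clean_reads", ]), 2)
    } else NA_real_
  )
}

#' Read-length distribution of a clean library
#'
#' @param clean a `clean_read_set`.
#' @param lengths lengths to tabulate (default 18:30).
#' @return named numeric vector of read-count-weighted proportions
#'   (sums to 1).
#' @export
length_distribution <- function(clean, lengths = 18:30) {
  stopifnot(inherits(clean, "clean_read_set"), clean$total_clean > 0)
  len <- nchar(clean$records$sequence)
  prop <- vapply(lengths, function(l)
    sum(clean$records$count[len == l]), numeric(1)) / clean$total_clean
  setNames(prop, as.character(lengths))
}

#' First-nucleotide bias at a stated read length
#'
#' Read-count-weighted first-base frequencies among clean sequences of
#' exactly `length` nt. Reported in the RNA alphabet (U, A, G, C).
#'
#' @param clean a `clean_read_set`, or a data.frame with columns
#'   `sequence` and `count`.
#' @param length sequence length to restrict to (default 21).
#' @return named numeric vector (U, A, G, C) summing to 1, or all-NA when
#'   no sequence of the stated length exists.
#' @export
first_base_bias <- function(clean, length = 21L) {
  records <- if (inherits(clean, "clean_read_set")) clean$records else clean
  stopifnot(all(c("sequence", "count") %in% names(records)))
  sel <- nchar(records$sequence) == length
  if (!any(sel)) {
    return(setNames(rep(NA_real_, 4), c("U", "A", "G", "C")))
  }
  first <- substr(.as_dna(records$sequence[sel]), 1, 1)
  counts <- records$count[sel]
  tot <- sum(counts)
  prop <- vapply(c("T", "A", "G", "C"), function(b)
    sum(counts[first == b]), numeric(1)) / tot
  setNames(prop, c("U", "A", "G", "C"))
}
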