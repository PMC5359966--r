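#' Trim 3' adapters from read sequences
#'
#' Small-RNA inserts are shorter than the read, so every genuine miRNA read
#' runs into the 3' adapter and must be trimmed before alignment. Matching is
#' 3'-anchored prefix matching under Hamming distance (no indels): the
#' leftmost read position where a prefix of the adapter aligns to the rest of
#' the read with error rate at most `max_error_rate` and overlap at least
#' `min_overlap` marks the cut; everything from that position on is removed.
#' A full internal adapter occurrence is the special case where the aligned
#' prefix is the whole adapter.
#'
#' @param seqs Character vector of read sequences.
#' @param adapter 3' adapter sequence (non-empty, DNA).
#' @param max_error_rate Maximum fraction of mismatching bases in the aligned
#'   window (default 0.1); must lie in `[0, 0.5)`.
#' @param min_overlap Minimum adapter prefix length considered (default 3 nt).
#' @return data.frame with columns `seq` (trimmed sequence), `had_adapter`
#'   (logical) and `original_len`.
#' @export
trim_adapter <- function(seqs, adapter, max_error_rate = 0.1, min_overlap = 3) {
  .check(nchar(adapter) > 0, "adapter must be non-empty")
  .check(max_error_rate >= 0 && max_error_rate < 0.5,
         "max_error_rate must be in [0, 0.5)")
  .check(min_overlap >= 1, "min_overlap must be >= 1")
  if (length(seqs) == 0L) {
    return(data.frame(seq = character(0), had_adapter = logical(0),
                      original_len = integer(0), stringsAsFactors = FALSE))
  }
  pos <- adapter_trim_cpp(seqs, adapter, max_error_rate, as.integer(min_overlap))
  had <- pos > 0L
  out <- seqs
  out[had] <- substr(seqs[had], 1L, pos[had] - 1L)
  data.frame(seq = out, had_adapter = had, original_len = nchar(seqs),
             stringsAsFactors = FALSE)
}

#' Discard reads shorter than a minimum length
#'
#' Trimmed reads shorter than 16 nt are too short to be confidently assigned
#' to a miRNA and are excluded from all further analysis.
#'
#' @param trimmed data.frame from [trim_adapter()] (or any data.frame with a
#'   `seq` column).
#' @param min_len Minimum surviving length in nt (default 16).
#' @return List with `reads` (the surviving rows) and `n_discarded`.
#' @export
length_filter <- function(trimmed, min_len = 16) {
  .check(min_len >= 1, "min_len must be >= 1")
  keep <- nchar(trimmed$seq) >= min_len
  list(reads = trimmed[keep, , drop = FALSE], n_discarded = sum(!keep))
}

#' Collapse identical reads within one sample
#'
#' @param seqs Character vector of read sequences.
#' @return Named integer vector: distinct sequence -> read count. Counts sum to
#'   `length(seqs)`.
#' @export
collapse_within <- function(seqs) {
  if (length(seqs) == 0L) return(stats::setNames(integer(0), character(0)))
  tab <- table(seqs)
  stats::setNames(as.integer(tab), names(tab))
}

#' Join per-sample collapsed reads into a unique-read count matrix
#'
#' Identical reads recur across samples of a study, so the union of per-sample
#' unique reads is far smaller than their concatenation; the downstream
#' alignment runs once over this union instead of once per sample.
#'
#' @param sample_counts Named list of named integer vectors (one per sample,
#'   from [collapse_within()]); list order fixes the sample/column order.
#' @return List with `seq` (character vector of distinct sequences, sorted) and
#'   `counts` (integer matrix, one row per sequence, one column per sample).
#' @export
collapse_joint <- function(sample_counts) {
  .check(length(sample_counts) >= 1, "at least one sample required")
  if (is.null(names(sample_counts))) {
    names(sample_counts) <- paste0("sample", seq_along(sample_counts))
  }
  all_seq <- sort(unique(unlist(lapply(sample_counts, names), use.names = FALSE)))
  counts <- matrix(0L, nrow = length(all_seq), ncol = length(sample_counts),
                   dimnames = list(NULL, names(sample_counts)))
  for (j in seq_along(sample_counts)) {
    sc <- sample_counts[[j]]
    if (length(sc)) counts[match(names(sc), all_seq), j] <- as.integer(sc)
  }
  list(seq = all_seq, counts = counts)
}

#' Preprocess raw reads of several samples into a unique-read table
#'
#' Runs adapter trimming, the minimum-length filter and within/across-sample
#' collapsing over in-memory read vectors. Identical raw reads are trimmed
#' once (trimming is a pure function of the sequence), which makes the stage
#' scale with the number of distinct reads rather than the number of reads.
#'
#' @param reads Named list of character vectors, one per sample (order fixes
#'   the sample order of every downstream table).
#' @param adapter 3' adapter sequence, or `NULL` to skip trimming.
#' @inheritParams trim_adapter
#' @inheritParams length_filter
#' @param discard_untrimmed Drop reads in which no adapter was found
#'   (default `FALSE`: such reads are kept; the adapter fraction is reported as
#'   QC instead).
#' @return List of class `mirtally_reads`: `seq`, `counts` (unique-read x
#'   sample matrix), and `stats` -- per sample `n_input`, `n_with_adapter`,
#'   `n_surviving`, `length_histogram` (surviving trimmed lengths).
#' @export
preprocess_reads <- function(reads, adapter, min_len = 16,
                             max_error_rate = 0.1, min_overlap = 3,
                             discard_untrimmed = FALSE) {
  .check(is.list(reads) && length(reads) >= 1, "reads must be a non-empty list")
  if (is.null(names(reads))) names(reads) <- paste0("sample", seq_along(reads))
  per_sample <- vector("list", length(reads))
  names(per_sample) <- names(reads)
  stats_list <- per_sample
  for (s in names(reads)) {
    raw <- collapse_within(reads[[s]])
    useq <- names(raw)
    cnt <- unname(raw)
    if (!is.null(adapter)) {
      tr <- trim_adapter(useq, adapter, max_error_rate, min_overlap)
    } else {
      tr <- data.frame(seq = useq, had_adapter = FALSE,
                       original_len = nchar(useq), stringsAsFactors = FALSE)
    }
    n_with_adapter <- sum(cnt[tr$had_adapter])
    if (discard_untrimmed) {
      keep0 <- tr$had_adapter
      tr <- tr[keep0, , drop = FALSE]; cnt <- cnt[keep0]
    }
    keep <- nchar(tr$seq) >= min_len
    surv_seq <- tr$seq[keep]
    surv_cnt <- cnt[keep]
    agg <- tapply(surv_cnt, surv_seq, sum)
    per_sample[[s]] <- stats::setNames(as.integer(agg), names(agg))
    lens <- nchar(surv_seq)
    hist <- tapply(surv_cnt, lens, sum)
    stats_list[[s]] <- list(
      n_input = length(reads[[s]]),
      n_with_adapter = n_with_adapter,
      n_surviving = sum(surv_cnt),
      length_histogram = stats::setNames(as.integer(hist), names(hist))
    )
  }
  joint <- collapse_joint(per_sample)
  structure(list(seq = joint$seq, counts = joint$counts, stats = stats_list),
            class = "mirtally_reads")
}

#' Preprocess FASTQ files into a unique-read table
#'
#' File-based wrapper around [preprocess_reads()].
#'
#' @param fastq_paths Named character vector of FASTQ paths (optionally
#'   gzipped); names become sample names (file basenames otherwise).
#' @inheritParams preprocess_reads
#' @return See [preprocess_reads()].
#' @export
preprocess_fastq <- function(fastq_paths, adapter, min_len = 16,
                             max_error_rate = 0.1, min_overlap = 3,
                             discard_untrimmed = FALSE) {
  if (is.null(names(fastq_paths))) {
    names(fastq_paths) <- sub("\\.(fastq|fq)(\\.gz)?$", "",
                              basename(fastq_paths))
  }
  reads <- lapply(fastq_paths, read_fastq_seqs)
  preprocess_reads(reads, adapter, min_len, max_error_rate, min_overlap,
                   discard_untrimmed)
}

#' @export
print.mirtally_reads <- function(x, ...) {
  tot <- colSums(x$counts)
  cat(sprintf("mirtally_reads: %d unique reads across %d sample(s)\n",
              length(x$seq), ncol(x$counts)))
  cat(sprintf("  surviving reads per sample: %s\n",
              paste(sprintf("%s=%d", colnames(x$counts), tot), collapse = ", ")))
  invisible(x)
}
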