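#' Run the full miRNA/isomiR quantification pipeline
#'
#' Takes preprocessed multi-sample unique reads and a built reference through
#' sequential annotation (miRNA -> hairpin -> small RNA -> mRNA), optional
#' genome remap invalidation of mismatch hits, cross-sample noise filtering,
#' and miRNA/isomiR count-table construction with mismatch-only companions and
#' RPM normalization.
#'
#' @param reads A `mirtally_reads` object from [preprocess_reads()] /
#'   [preprocess_fastq()].
#' @param reference A `mirna_reference` from [build_reference()].
#' @param smallrna,mrna Optional secondary references: FASTA path, data.frame
#'   with `id`/`seq`, or named character vector. `NULL` skips the tier.
#' @param genome Optional reference genome for remap invalidation (same
#'   accepted forms); `NULL` skips the step.
#' @param max_mm Per-stage mismatch bound, as in [annotate_cascade()]
#'   (default 1).
#' @param apply_filter Apply the cross-sample noise filter (default `TRUE`).
#' @param zero_fraction,min_mean,filter_mode Noise-filter parameters, see
#'   [filter_noise()].
#' @param rpm_denominator `"mirna_mapped"` (default; RPM columns sum to 1e6)
#'   or `"all_reads"` (surviving reads per sample).
#' @return An object of class `mirtally_run`: a list with `category` (per
#'   unique read), `hits` (valid flags and isomiR offsets), `multi_entry_reads`,
#'   `remap_stats`, `filter`, `mirna` (`standard`, `mismatch_only`, `rpm`),
#'   `isomir` (`standard`, `mismatch_only`, `keys`), `detected` (per-sample
#'   detected miRNAs before/after filtering), `qc` (per-sample QC table) and
#'   `offsets` (offset distribution over unique miRNA reads).
#' @export
run_pipeline <- function(reads, reference, smallrna = NULL, mrna = NULL,
                         genome = NULL, max_mm = 1, apply_filter = TRUE,
                         zero_fraction = 0.60, min_mean = 2,
                         filter_mode = c("OR", "AND"),
                         rpm_denominator = c("mirna_mapped", "all_reads")) {
  filter_mode <- match.arg(filter_mode)
  rpm_denominator <- match.arg(rpm_denominator)
  .check(inherits(reads, "mirtally_reads"), "reads must come from preprocess_reads()")
  .check(inherits(reference, "mirna_reference"),
         "reference must come from build_reference()")

  idx_mirna <- build_index(reference)
  idx_hairpin <- build_index(stats::setNames(reference$hairpin_groups$seq,
                                             reference$hairpin_groups$rep_id))
  idx_small <- if (!is.null(smallrna)) build_index(.as_ref_table(smallrna)) else NULL
  idx_mrna <- if (!is.null(mrna)) build_index(.as_ref_table(mrna)) else NULL

  cascade <- annotate_cascade(reads$seq, idx_mirna, idx_hairpin,
                              idx_small, idx_mrna, max_mm = max_mm)
  remap <- remap_invalidate(cascade$mirna_hits, reads$seq, genome, reads$counts)
  hits <- compute_offsets(remap$mirna_hits, reference$annotation)

  valid_hits <- hits[hits$valid, , drop = FALSE]
  pre <- count_mirna(hits, reads$counts)
  detected_pre <- colSums(pre$standard > 0)

  if (apply_filter) {
    filt <- filter_noise(reads$counts, zero_fraction, min_mean, filter_mode)
  } else {
    filt <- list(keep = rep(TRUE, nrow(reads$counts)), removed = FALSE,
                 stats = list(mode = "off",
                              n_reads_before = nrow(reads$counts),
                              n_reads_after = nrow(reads$counts),
                              counts_before = sum(reads$counts),
                              counts_after = sum(reads$counts)))
  }

  mirna <- count_mirna(hits, reads$counts, keep = filt$keep)
  isomir <- count_isomir(hits, reads$counts, keep = filt$keep)
  detected_post <- colSums(mirna$standard > 0)

  denom <- switch(rpm_denominator,
                  mirna_mapped = colSums(mirna$standard),
                  all_reads = vapply(reads$stats, function(s)
                    as.numeric(s$n_surviving), numeric(1)))
  rpm <- rpm_normalize(mirna$standard, denom)

  run <- structure(list(
    reads = reads,
    category = cascade$category,
    hits = hits,
    multi_entry_reads = cascade$multi_entry_reads,
    remap_stats = remap$stats,
    filter = filt,
    mirna = list(standard = mirna$standard, mismatch_only = mirna$mismatch_only,
                 rpm = rpm),
    isomir = isomir,
    detected = list(prefilter = detected_pre, postfilter = detected_post),
    params = list(max_mm = max_mm, apply_filter = apply_filter,
                  zero_fraction = zero_fraction, min_mean = min_mean,
                  filter_mode = filter_mode, rpm_denominator = rpm_denominator,
                  extension = reference$extension, mode = reference$mode)
  ), class = "mirtally_run")
  run$offsets <- compute_offset_distribution(valid_hits)
  run$qc <- compute_sample_qc(run)
  run
}

.as_ref_table <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    rec <- read_fasta_records(x)
    return(stats::setNames(rec$seq, rec$id))
  }
  x
}

#' @export
print.mirtally_run <- function(x, ...) {
  cat(sprintf("mirtally_run: %d samples, %d unique reads\n",
              ncol(x$reads$counts), length(x$reads$seq)))
  tab <- table(x$category)
  cat("  unique reads per category:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  miRNA entries quantified: %d (detected pre/post filter, mean per sample: %.1f/%.1f)\n",
              nrow(x$mirna$standard), mean(x$detected$prefilter),
              mean(x$detected$postfilter)))
  if (!is.na(x$remap_stats$rate_unique_pct)) {
    cat(sprintf("  remap invalidation: %.2f%% of unique mismatch reads (%.2f%% of counts)\n",
                x$remap_stats$rate_unique_pct, x$remap_stats$rate_total_pct))
  }
  invisible(x)
}
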