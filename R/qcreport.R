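#' Per-sample QC metrics
#'
#' Computes, for every sample, the trimming statistics, the annotation
#' breakdown (total and unique reads per category), the read redundancy
#' (total/unique; genuine miRNA libraries show high miRNA redundancy, so a
#' deviating pattern flags library problems such as primer dimers), the
#' count-weighted fraction of miRNA reads carrying mismatches, and the number
#' of detected miRNAs before and after the noise filter.
#'
#' @param run A `mirtally_run` from [run_pipeline()].
#' @return data.frame with one row per sample.
#' @export
compute_sample_qc <- function(run) {
  counts <- run$reads$counts
  cats <- levels(run$category)
  hit_mm <- rep(NA_integer_, length(run$reads$seq))
  hit_valid <- rep(FALSE, length(run$reads$seq))
  hit_mm[run$hits$seq_index] <- run$hits$mismatches
  hit_valid[run$hits$seq_index] <- run$hits$valid
  rows <- lapply(seq_len(ncol(counts)), function(j) {
    cs <- counts[, j]
    st <- run$reads$stats[[j]]
    row <- data.frame(sample = colnames(counts)[j],
                      n_raw = st$n_input,
                      n_with_adapter = st$n_with_adapter,
                      n_surviving = st$n_surviving,
                      stringsAsFactors = FALSE)
    for (cat in cats) {
      in_cat <- run$category == cat
      total <- sum(cs[in_cat])
      uniq <- sum(in_cat & cs > 0)
      row[[paste0("total_", cat)]] <- total
      row[[paste0("unique_", cat)]] <- uniq
      row[[paste0("redundancy_", cat)]] <- if (uniq > 0) total / uniq else NA_real_
    }
    mir_valid <- hit_valid & cs > 0
    denom <- sum(cs[mir_valid])
    row$mismatch_read_fraction <- if (denom > 0) {
      sum(cs[mir_valid & !is.na(hit_mm) & hit_mm >= 1L]) / denom
    } else NA_real_
    row$detected_mirnas_prefilter <- unname(run$detected$prefilter[j])
    row$detected_mirnas_postfilter <- unname(run$detected$postfilter[j])
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Distribution of 5'/3' end offsets over unique miRNA reads
#'
#' Summarises terminal variability of the aligned miRNA population: marginal
#' histograms of the 5' and 3' offsets, their joint table, and the fractions
#' of unique reads with no variation, 5' variation and 3' variation. The 5'
#' end is expected to vary far less than the 3' end because the seed region
#' (nucleotides 2-8) is functionally constrained, while 3' ends are exposed to
#' imprecise processing, exonucleolytic trimming and non-templated additions.
#'
#' @param hits_with_offsets Valid miRNA hit table carrying `offset5`/`offset3`
#'   (one row per unique read), from [compute_offsets()].
#' @return List of class `mirtally_offsets`: `hist5`, `hist3` (named counts),
#'   `joint` (data.frame `offset5`, `offset3`, `n`), `n_unique_reads` and
#'   `fractions` (`no_variation`, `five_prime`, `three_prime`, `both`).
#' @export
compute_offset_distribution <- function(hits_with_offsets) {
  h <- hits_with_offsets
  n <- nrow(h)
  if (n == 0L) {
    return(structure(list(hist5 = integer(0), hist3 = integer(0),
                          joint = data.frame(offset5 = integer(0),
                                             offset3 = integer(0), n = integer(0)),
                          n_unique_reads = 0L,
                          fractions = list(no_variation = NA_real_,
                                           five_prime = NA_real_,
                                           three_prime = NA_real_,
                                           both = NA_real_)),
                     class = "mirtally_offsets"))
  }
  t5 <- table(h$offset5)
  t3 <- table(h$offset3)
  jt <- as.data.frame(table(offset5 = h$offset5, offset3 = h$offset3),
                      stringsAsFactors = FALSE)
  jt <- jt[jt$Freq > 0, , drop = FALSE]
  joint <- data.frame(offset5 = as.integer(jt$offset5),
                      offset3 = as.integer(jt$offset3), n = jt$Freq)
  joint <- joint[order(joint$offset5, joint$offset3), , drop = FALSE]
  rownames(joint) <- NULL
  structure(list(
    hist5 = stats::setNames(as.integer(t5), names(t5)),
    hist3 = stats::setNames(as.integer(t3), names(t3)),
    joint = joint,
    n_unique_reads = n,
    fractions = list(
      no_variation = sum(h$offset5 == 0 & h$offset3 == 0) / n,
      five_prime = sum(h$offset5 != 0) / n,
      three_prime = sum(h$offset3 != 0) / n,
      both = sum(h$offset5 != 0 & h$offset3 != 0) / n
    )
  ), class = "mirtally_offsets")
}

#' Write machine-readable pipeline reports
#'
#' Emits the count tables, the per-sample QC summary (TSV and JSON), the
#' offset distribution tables and the filter/remap statistics to a directory.
#' Output is deterministic: identical runs produce byte-identical files.
#'
#' @param run A `mirtally_run` from [run_pipeline()].
#' @param dir Output directory (created if missing).
#' @param plots If `TRUE` and ggplot2 is available, also writes static PNG
#'   plots of the annotation breakdown and offset histograms under `plots/`.
#' @return Invisibly, the vector of files written.
#' @export
emit_reports <- function(run, dir, plots = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .check(dir.exists(dir), "cannot create output directory '%s'", dir)
  files <- character(0)
  wtsv <- function(df, name, rn = FALSE) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = rn,
                       col.names = if (rn) NA else TRUE)
    files <<- c(files, p)
    p
  }
  wtsv(run$qc, "qc_summary.tsv")
  wtsv(run$mirna$standard, "miRNA.counts.tsv", rn = TRUE)
  wtsv(run$mirna$mismatch_only, "miRNA.mismatch.counts.tsv", rn = TRUE)
  wtsv(run$mirna$rpm, "miRNA.rpm.tsv", rn = TRUE)
  iso <- cbind(run$isomir$keys, as.data.frame(run$isomir$standard))
  wtsv(iso, "isomiR.counts.tsv")
  iso_mm <- cbind(run$isomir$keys, as.data.frame(run$isomir$mismatch_only))
  wtsv(iso_mm, "isomiR.mismatch.counts.tsv")
  off <- run$offsets
  wtsv(data.frame(offset5 = names(off$hist5), n = off$hist5), "offsets5.tsv")
  wtsv(data.frame(offset3 = names(off$hist3), n = off$hist3), "offsets3.tsv")
  wtsv(off$joint, "offsets_joint.tsv")
  pj <- file.path(dir, "qc_summary.json")
  jsonlite::write_json(list(samples = run$qc,
                            multi_entry_reads = run$multi_entry_reads,
                            remap_stats = run$remap_stats,
                            offset_fractions = off$fractions),
                       pj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, pj)
  pf <- file.path(dir, "filter.stats.json")
  jsonlite::write_json(run$filter$stats, pf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, pf)
  if (plots && requireNamespace("ggplot2", quietly = TRUE)) {
    files <- c(files, .emit_plots(run, file.path(dir, "plots")))
  }
  invisible(files)
}

.emit_plots <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  qc <- run$qc
  cats <- levels(run$category)
  long <- do.call(rbind, lapply(cats, function(cat) {
    data.frame(sample = qc$sample, category = cat,
               reads = qc[[paste0("total_", cat)]])
  }))
  p1 <- ggplot2::ggplot(long, ggplot2::aes(x = .data$sample, y = .data$reads,
                                           fill = .data$category)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::labs(x = NULL, y = "reads", title = "Annotation breakdown") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  f1 <- file.path(dir, "annotation_breakdown.png")
  ggplot2::ggsave(f1, p1, width = 7, height = 4, dpi = 120)
  off <- rbind(
    data.frame(end = "5' offset", offset = as.integer(names(run$offsets$hist5)),
               n = unname(run$offsets$hist5)),
    data.frame(end = "3' offset", offset = as.integer(names(run$offsets$hist3)),
               n = unname(run$offsets$hist3))
  )
  p2 <- ggplot2::ggplot(off, ggplot2::aes(x = .data$offset, y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~end, scales = "free") +
    ggplot2::labs(x = "offset (nt)", y = "unique reads",
                  title = "End-offset distributions") +
    ggplot2::theme_bw()
  f2 <- file.path(dir, "offset_distributions.png")
  ggplot2::ggsave(f2, p2, width = 7, height = 3.5, dpi = 120)
  c(f1, f2)
}
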