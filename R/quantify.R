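#' Cross-sample noise filter for unique reads
#'
#' Genuine low-expressed miRNA reads recur across many samples of a study,
#' while background reads (degradation products, chance alignments) tend to
#' appear sporadically at low counts. A unique read is flagged as noise from
#' its count pattern across samples: its zero fraction (share of samples with
#' zero count) and its mean count. In `"OR"` mode (default) a read is removed
#' when `zero fraction > zero_fraction` OR `mean < min_mean`; in `"AND"` mode
#' both conditions must hold. Both combinations are offered because published
#' descriptions of this rule state it both ways; the mode in force is logged.
#'
#' @param counts Unique-read x sample integer matrix.
#' @param zero_fraction Zero-fraction threshold (default 0.60, strict `>`).
#' @param min_mean Mean-count threshold (default 2, strict `<`).
#' @param mode `"OR"` (default) or `"AND"`.
#' @return List with `keep` (logical per row), `removed` (logical), and
#'   `stats` (`mode`, `n_reads_before/after`, `counts_before/after`).
#' @export
filter_noise <- function(counts, zero_fraction = 0.60, min_mean = 2,
                         mode = c("OR", "AND")) {
  mode <- match.arg(mode)
  .check(zero_fraction >= 0 && zero_fraction <= 1,
         "zero_fraction must be in [0, 1]")
  .check(min_mean >= 0, "min_mean must be >= 0")
  zf <- rowMeans(counts == 0)
  mu <- rowMeans(counts)
  removed <- if (mode == "OR") (zf > zero_fraction) | (mu < min_mean)
             else (zf > zero_fraction) & (mu < min_mean)
  message(sprintf("noise filter (%s mode): removed %d of %d unique reads",
                  mode, sum(removed), nrow(counts)))
  list(keep = !removed, removed = removed,
       stats = list(mode = mode,
                    n_reads_before = nrow(counts),
                    n_reads_after = sum(!removed),
                    counts_before = sum(counts),
                    counts_after = sum(counts[!removed, , drop = FALSE])))
}

#' miRNA count matrices (standard and mismatch-only companion)
#'
#' Sums the per-sample counts of the kept, valid unique reads attributed to
#' each miRNA entry. The companion matrix counts only reads whose retained hit
#' carries at least one mismatch; subtracting it from the standard matrix
#' yields the perfect-match-only table without re-running the pipeline.
#'
#' @param mirna_hits Hit table from [annotate_cascade()] (optionally after
#'   [remap_invalidate()]).
#' @param counts Unique-read x sample count matrix (rows indexed by
#'   `seq_index`).
#' @param keep Optional logical vector over unique reads (from
#'   [filter_noise()]); `NULL` keeps all.
#' @param entries Optional character vector fixing the row universe; defaults
#'   to the entries observed among contributing reads.
#' @return List with integer matrices `standard` and `mismatch_only`
#'   (identical dimnames).
#' @export
count_mirna <- function(mirna_hits, counts, keep = NULL, entries = NULL) {
  use <- mirna_hits$valid
  if (!is.null(keep)) use <- use & keep[mirna_hits$seq_index]
  h <- mirna_hits[use, , drop = FALSE]
  if (is.null(entries)) entries <- sort(unique(h$entry_id))
  std <- .sum_by_feature(h$entry_id, counts[h$seq_index, , drop = FALSE],
                         entries, colnames(counts))
  mm <- h$mismatches >= 1L
  mmo <- .sum_by_feature(h$entry_id[mm], counts[h$seq_index[mm], , drop = FALSE],
                         entries, colnames(counts))
  list(standard = std, mismatch_only = mmo)
}

.sum_by_feature <- function(feature, counts, universe, sample_names) {
  out <- matrix(0L, nrow = length(universe), ncol = length(sample_names),
                dimnames = list(universe, sample_names))
  if (length(feature)) {
    agg <- rowsum(counts, group = feature)
    out[rownames(agg), ] <- as.integer(agg)
  }
  out
}

#' 5'/3' end offsets of miRNA hits (isomiR keys)
#'
#' An isomiR is identified by the displacement of the read's ends from the
#' annotated mature ends within the extended segment the read aligned to:
#' `offset5 = read start - mature start` (negative means the read begins
#' upstream, i.e. a longer 5' end) and `offset3 = read end - mature end`
#' (positive means a longer 3' end). `(0, 0)` is the canonical annotated
#' form. Reads aligning to a multi-segment entry take their offsets from the
#' first (lowest-index) segment that contains the placement; when the extended
#' contexts are identical the offsets coincide by construction.
#'
#' @param mirna_hits Hit table from [annotate_cascade()].
#' @param annotation Segment annotation from [build_reference()].
#' @return `mirna_hits` with `segment_index`, `offset5`, `offset3` columns
#'   appended.
#' @export
compute_offsets <- function(mirna_hits, annotation) {
  if (nrow(mirna_hits) == 0L) {
    mirna_hits$segment_index <- integer(0)
    mirna_hits$offset5 <- integer(0)
    mirna_hits$offset3 <- integer(0)
    return(mirna_hits)
  }
  mirna_hits$.row <- seq_len(nrow(mirna_hits))
  ann <- annotation[, c("entry_id", "segment_index", "seg_start",
                        "mature_start", "mature_end", "flank3")]
  m <- merge(mirna_hits, ann, by = "entry_id")
  seg_end <- m$mature_end + m$flank3
  inside <- m$start >= m$seg_start & m$end <= seg_end
  m <- m[inside, , drop = FALSE]
  if (anyNA(match(mirna_hits$.row, m$.row))) {
    stop("miRNA hit not contained in any segment; delimiter contract violated",
         call. = FALSE)
  }
  m <- m[order(m$.row, m$segment_index), , drop = FALSE]
  m <- m[!duplicated(m$.row), , drop = FALSE]
  m <- m[order(m$.row), , drop = FALSE]
  out <- mirna_hits
  out$segment_index <- m$segment_index
  out$offset5 <- m$start - m$mature_start
  out$offset3 <- m$end - m$mature_end
  out$.row <- NULL
  out
}

#' isomiR count matrices keyed by (entry, 5' offset, 3' offset)
#'
#' Distinct sequences sharing the same entry and end offsets are summed into
#' one isomiR row; per entry, isomiR rows sum to the miRNA count for every
#' sample.
#'
#' @param hits_with_offsets Hit table from [compute_offsets()].
#' @inheritParams count_mirna
#' @return List with matrices `standard`, `mismatch_only` (rownames of the
#'   form `entry|offset5|offset3`) and `keys` (data.frame `entry_id`,
#'   `offset5`, `offset3` aligned to the rows).
#' @export
count_isomir <- function(hits_with_offsets, counts, keep = NULL) {
  .check(all(c("offset5", "offset3") %in% names(hits_with_offsets)),
         "run compute_offsets() first")
  use <- hits_with_offsets$valid
  if (!is.null(keep)) use <- use & keep[hits_with_offsets$seq_index]
  h <- hits_with_offsets[use, , drop = FALSE]
  key <- paste(h$entry_id, h$offset5, h$offset3, sep = "|")
  universe <- sort(unique(key))
  std <- .sum_by_feature(key, counts[h$seq_index, , drop = FALSE],
                         universe, colnames(counts))
  mm <- h$mismatches >= 1L
  mmo <- .sum_by_feature(key[mm], counts[h$seq_index[mm], , drop = FALSE],
                         universe, colnames(counts))
  parts <- strsplit(universe, "|", fixed = TRUE)
  keys <- data.frame(
    entry_id = vapply(parts, `[[`, character(1), 1L),
    offset5 = as.integer(vapply(parts, `[[`, character(1), 2L)),
    offset3 = as.integer(vapply(parts, `[[`, character(1), 3L)),
    stringsAsFactors = FALSE
  )
  list(standard = std, mismatch_only = mmo, keys = keys)
}

#' Reads-per-million normalization
#'
#' Scales each column by `1e6 / denominator`. With the default miRNA-mapped
#' denominator (the column sums of the matrix itself) every non-empty sample's
#' RPM column sums to exactly one million; a library-size denominator can be
#' supplied instead (e.g. surviving reads per sample).
#'
#' @param mat Count matrix (features x samples).
#' @param denominators Optional numeric vector of per-sample denominators
#'   (recycled names-matched to columns); `NULL` uses `colSums(mat)`.
#' @return Real-valued matrix of the same shape. Samples with a zero
#'   denominator yield `NA` columns with a warning.
#' @export
rpm_normalize <- function(mat, denominators = NULL) {
  if (is.null(denominators)) denominators <- colSums(mat)
  if (!is.null(names(denominators)) && !is.null(colnames(mat))) {
    denominators <- denominators[colnames(mat)]
  }
  .check(length(denominators) == ncol(mat),
         "need one denominator per sample column")
  zero <- denominators == 0
  if (any(zero)) {
    warning(sprintf("zero denominator for sample(s) %s; RPM reported as NA",
                    paste(colnames(mat)[zero], collapse = ", ")), call. = FALSE)
    denominators[zero] <- NA_real_
  }
  sweep(mat, 2L, denominators, function(x, d) x * 1e6 / d)
}
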