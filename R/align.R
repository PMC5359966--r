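#' Build an alignment index over a reference
#'
#' Concatenates the reference entries into a single subject string with `N`
#' padding between entries (reads can never align across `N`, so placements
#' are confined to one entry) and records each entry's offset. The scan itself
#' is an exhaustive compiled Hamming search: miRNA-scale references are a few
#' kilobases, so the exhaustive scan is exact by construction and still fast.
#'
#' @param reference One of: a `mirna_reference` (its delimited entries are
#'   indexed), a data.frame with `entry_id`/`id` and `seq` columns, or a named
#'   character vector of sequences.
#' @return An object of class `read_index` with the concatenated subject and
#'   the entry offset table.
#' @export
build_index <- function(reference) {
  if (inherits(reference, "mirna_reference")) {
    ids <- reference$entries$entry_id
    seqs <- reference$entries$seq
  } else if (is.data.frame(reference)) {
    ids <- if ("entry_id" %in% names(reference)) reference$entry_id else reference$id
    seqs <- reference$seq
  } else {
    .check(!is.null(names(reference)), "a character reference must be named")
    ids <- names(reference)
    seqs <- unname(reference)
  }
  .check(length(seqs) > 0, "reference is empty")
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  sep <- 2L  # >= 1 N between entries; N voids any placement crossing it
  offsets <- cumsum(c(0L, utils::head(lens + sep, -1L)))
  subject <- paste(seqs, collapse = strrep("N", sep))
  structure(list(subject = subject, entry_id = ids, offset = offsets,
                 length = lens), class = "read_index")
}

#' Align reads to an indexed reference with bounded mismatches
#'
#' Reports all placements of each read with Hamming distance at most `max_mm`.
#' Alignment is sense-only by default: small-RNA libraries are stranded (the
#' adapters are ligated to the RNA itself), so a read must come from the
#' forward reference strand, and searching the reverse complement would
#' cross-assign reads between reverse-complementary miRNA arm pairs. `N`
#' never matches any base: an `N` in the read costs a mismatch, and a
#' placement covering a reference delimiter `N` is rejected outright. Only the
#' minimum-mismatch stratum of each read is retained, with leftmost placements
#' first.
#'
#' @param seqs Character vector of read sequences (each >= 1 nt).
#' @param index A `read_index` from [build_index()].
#' @param max_mm Maximum Hamming mismatches (default 1).
#' @param sense_only If `FALSE`, the reverse complement of each read is also
#'   searched and reported with `strand = "-"` (diagnostic mode only).
#' @return data.frame with columns `seq_index`, `entry_id`, `start`, `end`
#'   (0-based half-open within the entry sequence), `mismatches`, `strand`.
#' @export
align_reads <- function(seqs, index, max_mm = 1, sense_only = TRUE) {
  .check(inherits(index, "read_index"), "index must come from build_index()")
  empty <- data.frame(seq_index = integer(0), entry_id = character(0),
                      start = integer(0), end = integer(0),
                      mismatches = integer(0), strand = character(0),
                      stringsAsFactors = FALSE)
  if (length(seqs) == 0L) return(empty)
  scan1 <- hamming_scan_cpp(index$subject, seqs, as.integer(max_mm))
  scan1$strand <- rep("+", nrow(scan1))
  hits <- scan1
  if (!sense_only) {
    scan2 <- hamming_scan_cpp(index$subject, revcomp(seqs), as.integer(max_mm))
    scan2$strand <- rep("-", nrow(scan2))
    hits <- rbind(hits, scan2)
  }
  if (nrow(hits) == 0L) return(empty)
  # map subject coordinates back to entries (placements cannot cross the N
  # padding, so the whole span lies in the entry found for its start)
  ei <- findInterval(hits$start - 1L, index$offset)
  qlen <- nchar(seqs)[hits$query]
  out <- data.frame(
    seq_index = hits$query,
    entry_id = index$entry_id[ei],
    start = hits$start - 1L - index$offset[ei],
    end = hits$start - 1L - index$offset[ei] + qlen,
    mismatches = hits$mismatches,
    strand = hits$strand,
    stringsAsFactors = FALSE
  )
  # minimum-mismatch stratum per read
  min_mm <- tapply(out$mismatches, out$seq_index, min)
  out <- out[out$mismatches == unname(min_mm[as.character(out$seq_index)]), ,
             drop = FALSE]
  out <- out[order(out$seq_index, out$entry_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sequentially annotate unique reads against reference tiers
#'
#' Each read is assigned the first category, in the fixed order miRNA ->
#' hairpin -> small RNA -> mRNA, in which it aligns with at most the stage's
#' mismatch bound; reads aligning nowhere are `unaligned`. Categories are
#' therefore mutually exclusive and exhaustive. For the miRNA stage the best
#' hit of each read is retained for quantification: among minimum-mismatch
#' placements the read is attributed to the lexicographically smallest entry
#' id (and the leftmost placement within it) and counted once; reads whose
#' minimum-mismatch placements span several entries are tallied in a
#' `multi_entry_reads` counter rather than double-counted.
#'
#' @param seqs Character vector of unique read sequences.
#' @param mirna_index `read_index` over the extended miRNA reference
#'   (mandatory).
#' @param hairpin_index,smallrna_index,mrna_index Optional `read_index`es for
#'   the later tiers; `NULL` skips the tier.
#' @param max_mm Mismatch bound per stage: a single number or a named vector
#'   with any of `miRNA`, `hairpin`, `smallRNA`, `mRNA` (default 1 each).
#' @return List with `category` (factor per read with levels miRNA, hairpin,
#'   smallRNA, mRNA, unaligned), `mirna_hits` (one row per miRNA-assigned
#'   read: `seq_index`, `entry_id`, `start`, `end`, `mismatches`, `valid`),
#'   and `multi_entry_reads` (count of ambiguous unique reads).
#' @export
annotate_cascade <- function(seqs, mirna_index, hairpin_index = NULL,
                             smallrna_index = NULL, mrna_index = NULL,
                             max_mm = 1) {
  .check(!is.null(mirna_index), "the miRNA reference is mandatory")
  stages <- list(miRNA = mirna_index, hairpin = hairpin_index,
                 smallRNA = smallrna_index, mRNA = mrna_index)
  .check(length(max_mm) == 1L || !is.null(names(max_mm)),
         "max_mm must be a single bound or a named per-stage vector")
  mm <- rep_len(if (length(max_mm) == 1L) unname(max_mm) else 1, 4L)
  names(mm) <- names(stages)
  if (!is.null(names(max_mm))) mm[names(max_mm)] <- max_mm
  category <- rep("unaligned", length(seqs))
  unassigned <- seq_along(seqs)
  mirna_hits <- NULL
  multi_entry <- 0L
  for (stage in names(stages)) {
    idx <- stages[[stage]]
    if (is.null(idx)) next
    if (length(unassigned) == 0L) break
    hits <- align_reads(seqs[unassigned], idx, max_mm = mm[[stage]])
    if (nrow(hits) == 0L) next
    hits$seq_index <- unassigned[hits$seq_index]
    hit_reads <- unique(hits$seq_index)
    category[hit_reads] <- stage
    if (stage == "miRNA") {
      sel <- .best_mirna_hit(hits)
      mirna_hits <- sel$best
      multi_entry <- sel$multi_entry
    }
    unassigned <- setdiff(unassigned, hit_reads)
  }
  if (is.null(mirna_hits)) {
    mirna_hits <- data.frame(seq_index = integer(0), entry_id = character(0),
                             start = integer(0), end = integer(0),
                             mismatches = integer(0), valid = logical(0),
                             stringsAsFactors = FALSE)
  }
  list(
    category = factor(category,
                      levels = c("miRNA", "hairpin", "smallRNA", "mRNA", "unaligned")),
    mirna_hits = mirna_hits,
    multi_entry_reads = multi_entry
  )
}

# one retained hit per read: smallest entry_id among the minimum-mismatch
# stratum, leftmost placement within that entry
.best_mirna_hit <- function(hits) {
  ord <- order(hits$seq_index, hits$entry_id, hits$start)
  hits <- hits[ord, , drop = FALSE]
  first <- !duplicated(hits$seq_index)
  n_entries <- tapply(hits$entry_id, hits$seq_index, function(e) length(unique(e)))
  best <- hits[first, c("seq_index", "entry_id", "start", "end", "mismatches"),
               drop = FALSE]
  best$valid <- TRUE
  rownames(best) <- NULL
  list(best = best, multi_entry = sum(n_entries > 1L))
}

#' Invalidate mismatch hits that remap perfectly to a genome
#'
#' A read that aligns to a miRNA entry only with mismatches, yet occurs
#' verbatim somewhere in the reference genome, most likely originates from
#' that genomic locus and not from the miRNA; its miRNA assignment is
#' invalidated. Both genome strands are searched (the true origin's strand is
#' unknown) and only exact, zero-mismatch occurrences count. Perfect-match
#' miRNA hits are never candidates, so a read matching its own miRNA locus is
#' untouched. The step is optional: with `genome = NULL` every hit stays
#' valid.
#'
#' @param mirna_hits Hit table from [annotate_cascade()].
#' @param seqs The unique-read sequences the `seq_index` column refers to.
#' @param genome `NULL`, a FASTA path, a data.frame with `id`/`seq`, or a
#'   character vector of contig sequences.
#' @param counts Optional unique-read x sample count matrix; enables the
#'   count-weighted invalidation rate in the returned stats.
#' @return List with `mirna_hits` (the `valid` column updated) and `stats`:
#'   `n_candidates`, `n_invalidated`, `rate_unique_pct` (share of unique
#'   mismatch reads invalidated) and `rate_total_pct` (share of total mismatch
#'   read counts invalidated; `NA` without `counts`).
#' @export
remap_invalidate <- function(mirna_hits, seqs, genome, counts = NULL) {
  stats0 <- list(n_candidates = 0L, n_invalidated = 0L,
                 rate_unique_pct = NA_real_, rate_total_pct = NA_real_)
  if (is.null(genome) || nrow(mirna_hits) == 0L) {
    return(list(mirna_hits = mirna_hits, stats = stats0))
  }
  contigs <- if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    read_fasta_records(genome)$seq
  } else if (is.data.frame(genome)) {
    genome$seq
  } else {
    as.character(genome)
  }
  contigs <- toupper(contigs)
  cand <- which(mirna_hits$mismatches >= 1L & mirna_hits$valid)
  stats0$n_candidates <- length(cand)
  if (length(cand) == 0L) return(list(mirna_hits = mirna_hits, stats = stats0))
  subjects <- c(contigs, revcomp(contigs))
  invalid <- exact_occurs_cpp(seqs[mirna_hits$seq_index[cand]], subjects)
  mirna_hits$valid[cand[invalid]] <- FALSE
  stats0$n_invalidated <- sum(invalid)
  stats0$rate_unique_pct <- 100 * sum(invalid) / length(cand)
  if (!is.null(counts)) {
    cand_counts <- rowSums(counts[mirna_hits$seq_index[cand], , drop = FALSE])
    stats0$rate_total_pct <- 100 * sum(cand_counts[invalid]) / sum(cand_counts)
  }
  list(mirna_hits = mirna_hits, stats = stats0)
}
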