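#' Collapse identical sequences into groups
#'
#' miRBase contains mature miRNAs (and, less often, hairpins) with byte-identical
#' sequences under different names, e.g. paralog expansions where the mature
#' sequence is conserved while flanking genomic sequence diverged. Identical
#' records are collapsed into one group represented by the lexicographically
#' smallest member id; all member ids are preserved for traceability.
#'
#' @param records data.frame with columns `id` and `seq`
#'   (from [read_fasta_records()]).
#' @return data.frame with one row per distinct sequence: `rep_id`, `seq`,
#'   `n_members`, `member_ids` (comma-separated, sorted), ordered by `rep_id`.
#' @export
dedup_sequences <- function(records) {
  if (nrow(records) == 0L) {
    return(data.frame(rep_id = character(0), seq = character(0),
                      n_members = integer(0), member_ids = character(0),
                      stringsAsFactors = FALSE))
  }
  grp <- split(records$id, records$seq)
  members <- lapply(grp, function(ids) sort(ids))
  out <- data.frame(
    rep_id = vapply(members, `[[`, character(1), 1L),
    seq = names(grp),
    n_members = lengths(members),
    member_ids = vapply(members, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$rep_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Locate mature miRNAs on hairpin precursors
#'
#' Reports every exact sense-strand substring occurrence of each deduplicated
#' mature sequence in each deduplicated hairpin. A mature may occur in several
#' hairpins (multi-precursor matures) or several times in one hairpin; all
#' occurrences are reported. The reverse strand is never searched: the library
#' protocol is stranded and the reference is sense-only throughout.
#'
#' @param matures,hairpins Group tables from [dedup_sequences()].
#' @return data.frame with columns `mature_id` (group rep), `hairpin_id`
#'   (group rep), `start`, `end` (0-based half-open in the hairpin sequence).
#'   Matures with zero occurrences are dropped with a warning and listed in the
#'   `"orphans"` attribute.
#' @export
map_matures_to_hairpins <- function(matures, hairpins) {
  empty <- data.frame(mature_id = character(0), hairpin_id = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(matures) == 0L || nrow(hairpins) == 0L) {
    attr(empty, "orphans") <- matures$rep_id
    return(empty)
  }
  subj <- Biostrings::DNAStringSet(hairpins$seq)
  res <- lapply(seq_len(nrow(matures)), function(i) {
    m <- Biostrings::vmatchPattern(matures$seq[i], subj)
    starts <- Biostrings::startIndex(m)
    starts[vapply(starts, is.null, logical(1))] <- list(integer(0))
    n_hit <- lengths(starts)
    if (sum(n_hit) == 0L) return(NULL)
    hp <- rep(hairpins$rep_id, n_hit)
    st <- unlist(starts, use.names = FALSE)
    data.frame(mature_id = matures$rep_id[i], hairpin_id = hp,
               start = st - 1L, end = st - 1L + nchar(matures$seq[i]),
               stringsAsFactors = FALSE)
  })
  occ <- do.call(rbind, res)
  if (is.null(occ)) occ <- empty
  occ <- occ[order(occ$mature_id, occ$hairpin_id, occ$start), , drop = FALSE]
  rownames(occ) <- NULL
  orphans <- setdiff(matures$rep_id, occ$mature_id)
  if (length(orphans)) {
    warning(sprintf("%d mature group(s) have no hairpin occurrence and are excluded: %s",
                    length(orphans), paste(orphans, collapse = ", ")),
            call. = FALSE)
  }
  attr(occ, "orphans") <- orphans
  occ
}

#' Cluster overlapping mature miRNAs
#'
#' Two mature groups belong to the same cluster when they are connected by a
#' chain of pairwise interval overlaps on a shared hairpin (or by shared group
#' membership). This is the connected-components relation on the overlap graph;
#' components are computed with igraph. Overlapping matures on one precursor
#' produce nearly indistinguishable reads once end variation is allowed, which
#' is why they can optionally be quantified as one cluster entry.
#'
#' @param occurrences Occurrence table from [map_matures_to_hairpins()].
#' @return data.frame with columns `mature_id`, `cluster_id`; the cluster id is
#'   the lexicographically smallest member id, making it deterministic.
#' @export
cluster_matures <- function(occurrences) {
  if (nrow(occurrences) == 0L) {
    return(data.frame(mature_id = character(0), cluster_id = character(0),
                      stringsAsFactors = FALSE))
  }
  verts <- sort(unique(occurrences$mature_id))
  edges <- character(0)
  for (hp in unique(occurrences$hairpin_id)) {
    sub <- occurrences[occurrences$hairpin_id == hp, , drop = FALSE]
    if (nrow(sub) < 2L) next
    for (i in seq_len(nrow(sub) - 1L)) {
      for (j in seq.int(i + 1L, nrow(sub))) {
        if (sub$start[i] < sub$end[j] && sub$start[j] < sub$end[i] &&
            sub$mature_id[i] != sub$mature_id[j]) {
          edges <- c(edges, sub$mature_id[i], sub$mature_id[j])
        }
      }
    }
  }
  g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(verts)
  if (length(edges)) g <- g + igraph::edges(edges)
  comp <- igraph::components(g)$membership
  cl_id <- vapply(split(names(comp), comp), min, character(1))
  data.frame(mature_id = names(comp),
             cluster_id = unname(cl_id[as.character(comp)]),
             stringsAsFactors = FALSE)[order(names(comp)), , drop = FALSE]
}

#' Extend a mature occurrence with hairpin flanks
#'
#' Adds up to `extension` nucleotides of precursor sequence on each side of the
#' annotated mature, clipped at the hairpin boundaries. Flank bases are lower
#' case, mature bases upper case, so the case carries the annotation through to
#' the alignment reference.
#'
#' @param hairpin_seq Hairpin sequence (uppercase DNA).
#' @param start,end 0-based half-open mature coordinates on the hairpin.
#' @param extension Maximum flank length per side (nt), `>= 0`.
#' @return List with `segment_seq`, `flank5`, `flank3`,
#'   `mature_start_in_segment` (0-based, equals `flank5`) and `mature_len`.
#' @export
extend_mature <- function(hairpin_seq, start, end, extension) {
  .check(extension >= 0, "extension must be >= 0")
  L <- nchar(hairpin_seq)
  .check(start >= 0 && start < end && end <= L,
         "mature coordinates [%d,%d) outside hairpin of length %d", start, end, L)
  f5 <- min(extension, start)
  f3 <- min(extension, L - end)
  seg <- paste0(
    tolower(substr(hairpin_seq, start - f5 + 1L, start)),
    toupper(substr(hairpin_seq, start + 1L, end)),
    tolower(substr(hairpin_seq, end + 1L, end + f3))
  )
  list(segment_seq = seg, flank5 = f5, flank3 = f3,
       mature_start_in_segment = f5, mature_len = end - start)
}

#' Assemble the extended, delimited alignment reference
#'
#' Concatenates the extended segments of each entry, joining segments that
#' carry the same mature sequence with a single `N` and, in per-cluster mode,
#' segments of different matures with `NN`. The delimiters partition the entry
#' so that no read can align across two segments (`N` never matches a base).
#'
#' @param occurrences Occurrence table from [map_matures_to_hairpins()].
#' @param matures,hairpins Group tables from [dedup_sequences()].
#' @param clusters Cluster table from [cluster_matures()] (required for
#'   `mode = "per-cluster"`).
#' @param extension Flank length per side (nt); default 4, enough to represent
#'   5' offsets of +/-1 and 3' offsets of +/-3 nt.
#' @param mode `"per-mature"` (one entry per deduplicated mature; default) or
#'   `"per-cluster"` (one entry per overlap cluster).
#' @return List with `entries` (data.frame `entry_id`, `seq`) and `annotation`
#'   (one row per segment: `entry_id`, `segment_index`, `hairpin_id`,
#'   `mature_id`, `member_ids`, `seg_start`, `mature_start`, `mature_end`
#'   -- 0-based half-open offsets within the entry sequence -- `flank5`,
#'   `flank3`).
#' @export
assemble_reference <- function(occurrences, matures, hairpins, clusters = NULL,
                               extension = 4, mode = c("per-mature", "per-cluster")) {
  mode <- match.arg(mode)
  hp_seq <- stats::setNames(hairpins$seq, hairpins$rep_id)
  m_members <- stats::setNames(matures$member_ids, matures$rep_id)
  occ <- occurrences[order(occurrences$mature_id, occurrences$hairpin_id,
                           occurrences$start), , drop = FALSE]
  if (mode == "per-mature") {
    occ$entry_id <- occ$mature_id
  } else {
    .check(!is.null(clusters), "per-cluster mode requires a cluster table")
    cl <- stats::setNames(clusters$cluster_id, clusters$mature_id)
    occ$entry_id <- unname(cl[occ$mature_id])
    occ <- occ[order(occ$entry_id, occ$mature_id, occ$hairpin_id, occ$start), ,
               drop = FALSE]
  }
  ann_rows <- list()
  entry_ids <- character(0)
  entry_seqs <- character(0)
  for (eid in unique(occ$entry_id)) {
    sub <- occ[occ$entry_id == eid, , drop = FALSE]
    full <- ""
    prev_mature <- NULL
    for (i in seq_len(nrow(sub))) {
      seg <- extend_mature(hp_seq[[sub$hairpin_id[i]]], sub$start[i],
                           sub$end[i], extension)
      if (i > 1L) {
        delim <- if (identical(prev_mature, sub$mature_id[i])) "N" else "NN"
        full <- paste0(full, delim)
      }
      seg_start <- nchar(full)
      full <- paste0(full, seg$segment_seq)
      ann_rows[[length(ann_rows) + 1L]] <- data.frame(
        entry_id = eid, segment_index = i,
        hairpin_id = sub$hairpin_id[i], mature_id = sub$mature_id[i],
        member_ids = unname(m_members[sub$mature_id[i]]),
        seg_start = seg_start,
        mature_start = seg_start + seg$flank5,
        mature_end = seg_start + seg$flank5 + seg$mature_len,
        flank5 = seg$flank5, flank3 = seg$flank3,
        stringsAsFactors = FALSE
      )
      prev_mature <- sub$mature_id[i]
    }
    if (eid %in% entry_ids) stop(sprintf("duplicate entry id '%s'", eid), call. = FALSE)
    entry_ids <- c(entry_ids, eid)
    entry_seqs <- c(entry_seqs, full)
  }
  list(
    entries = data.frame(entry_id = entry_ids, seq = entry_seqs,
                         stringsAsFactors = FALSE),
    annotation = do.call(rbind, ann_rows)
  )
}

#' Build the full miRNA alignment reference from FASTA inputs
#'
#' End-to-end reference construction: parse mature and hairpin FASTA, collapse
#' identical sequences, locate matures on hairpins, cluster overlapping
#' matures, extend each occurrence with hairpin flanks, and assemble the
#' delimited reference entries plus their annotation.
#'
#' @param mature_path,hairpin_path FASTA files (miRBase dialect).
#' @param species Optional id prefix filter, e.g. `"hsa-"`.
#' @inheritParams assemble_reference
#' @return An object of class `mirna_reference`: a list with `mature_groups`,
#'   `hairpin_groups`, `occurrences`, `clusters`, `orphans`, `entries`,
#'   `annotation`, `extension`, `mode`.
#' @export
build_reference <- function(mature_path, hairpin_path, species = NULL,
                            extension = 4, mode = c("per-mature", "per-cluster")) {
  mode <- match.arg(mode)
  matures <- dedup_sequences(read_fasta_records(mature_path, species))
  hairpins <- dedup_sequences(read_fasta_records(hairpin_path, species))
  occ <- map_matures_to_hairpins(matures, hairpins)
  clusters <- cluster_matures(occ)
  asm <- assemble_reference(occ, matures, hairpins, clusters, extension, mode)
  structure(list(
    mature_groups = matures, hairpin_groups = hairpins,
    occurrences = occ, clusters = clusters,
    orphans = attr(occ, "orphans"),
    entries = asm$entries, annotation = asm$annotation,
    extension = extension, mode = mode
  ), class = "mirna_reference")
}

#' @export
print.mirna_reference <- function(x, ...) {
  cat(sprintf("mirna_reference: %d entries (%s mode, extension %d nt)\n",
              nrow(x$entries), x$mode, x$extension))
  cat(sprintf("  mature groups: %d (from %d records), hairpin groups: %d\n",
              nrow(x$mature_groups), sum(x$mature_groups$n_members),
              nrow(x$hairpin_groups)))
  cat(sprintf("  occurrences: %d, clusters: %d, orphan matures: %d\n",
              nrow(x$occurrences), length(unique(x$clusters$cluster_id)),
              length(x$orphans)))
  invisible(x)
}

#' Write a built reference to disk
#'
#' Emits the case- and delimiter-encoded reference FASTA, the deduplicated
#' hairpin FASTA, and TSV tables for the segment annotation (1-based inclusive
#' coordinates, stated in the header) and the identical-sequence groups.
#'
#' @param ref A `mirna_reference` from [build_reference()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_reference <- function(ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref_fa <- file.path(dir, "reference.fa")
  write_fasta(ref$entries$entry_id, ref$entries$seq, ref_fa)
  hp_fa <- file.path(dir, "hairpin.fa")
  write_fasta(ref$hairpin_groups$rep_id, ref$hairpin_groups$seq, hp_fa)
  ann <- ref$annotation
  ann_out <- data.frame(
    entry_id = ann$entry_id, segment_index = ann$segment_index,
    hairpin_id = ann$hairpin_id, mature_id = ann$mature_id,
    member_ids = ann$member_ids,
    mature_start_1based = ann$mature_start + 1L,
    mature_end_1based = ann$mature_end,
    flank5 = ann$flank5, flank3 = ann$flank3
  )
  ann_tsv <- file.path(dir, "annotation.tsv")
  con <- file(ann_tsv, "w")
  writeLines("# mature coordinates are 1-based inclusive within the entry sequence", con)
  utils::write.table(ann_out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  grp_files <- c(mature = file.path(dir, "mature_groups.tsv"),
                 hairpin = file.path(dir, "hairpin_groups.tsv"))
  utils::write.table(ref$mature_groups, grp_files["mature"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ref$hairpin_groups, grp_files["hairpin"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(ref_fa, hp_fa, ann_tsv, unname(grp_files)))
}
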