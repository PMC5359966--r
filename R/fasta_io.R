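#' Read a miRBase-style FASTA file
#'
#' Parses mature-miRNA or hairpin FASTA in the miRBase dialect: headers of the
#' form `>id free description`, sequences possibly in the RNA alphabet and in
#' mixed case. `U`/`u` is converted to `T` and all bases are upper-cased, so
#' downstream code works on a single DNA alphabet.
#'
#' @param path Path to a FASTA file (plain or gzip-compressed).
#' @param species Optional identifier prefix (e.g. `"hsa-"`); records whose id
#'   does not start with it are dropped.
#' @return A data.frame with columns `id`, `seq` (uppercase DNA) and
#'   `description`.
#' @details Records containing characters outside `A,C,G,T,U,N`
#'   (case-insensitive) raise an error naming the offending record, as do
#'   duplicated ids. An empty file yields a zero-row data.frame.
#' @export
read_fasta_records <- function(path, species = NULL) {
  .check(file.exists(path), "FASTA file not found: %s", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop(sprintf("malformed FASTA in '%s': %s", path,
                                     conditionMessage(e)), call. = FALSE)
  )
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(set))
  seqs <- chartr("U", "T", seqs)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop(sprintf("record '%s' in '%s' contains characters outside A,C,G,T,U,N",
                 ids[which(bad)[1]], path), call. = FALSE)
  }
  if (!is.null(species)) {
    keep <- startsWith(ids, species)
    ids <- ids[keep]; seqs <- seqs[keep]; desc <- desc[keep]
  }
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate sequence id '%s' in '%s'",
                 ids[duplicated(ids)][1], path), call. = FALSE)
  }
  if (length(ids) && any(nchar(seqs) == 0L)) {
    stop(sprintf("record '%s' in '%s' has an empty sequence",
                 ids[which(nchar(seqs) == 0L)[1]], path), call. = FALSE)
  }
  data.frame(id = ids, seq = seqs, description = desc,
             stringsAsFactors = FALSE)
}

#' Write sequences to FASTA
#'
#' Case is preserved (the extended reference encodes mature regions in upper
#' case and flanks in lower case).
#'
#' @param ids Character vector of identifiers.
#' @param seqs Character vector of sequences.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(ids, seqs, path) {
  set <- Biostrings::BStringSet(seqs)
  names(set) <- ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read read sequences from FASTQ
#'
#' Quality strings are parsed but not used: the quantification pipeline applies
#' no base-quality filtering.
#'
#' @param path Path to a FASTQ file, optionally gzip-compressed.
#' @return Character vector of uppercase read sequences.
#' @export
read_fastq_seqs <- function(path) {
  .check(file.exists(path), "FASTQ file not found: %s", path)
  set <- Biostrings::readDNAStringSet(path, format = "fastq")
  toupper(as.character(set))
}
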