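#' Reverse-complement DNA strings
#'
#' Vectorised reverse complement over the DNA alphabet (including `N`).
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp(c("ACGT", "AAN"))
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Random DNA sequences
#'
#' @param n Number of sequences.
#' @param len Length of each sequence (recycled).
#' @return Character vector of `n` uppercase DNA sequences.
#' @keywords internal
random_dna <- function(n, len) {
  len <- rep_len(len, n)
  vapply(len, function(l) {
    paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = "")
  }, character(1))
}

#' @useDynLib mirtally, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

utils::globalVariables(".data")

# stopifnot-style check with a formatted message
.check <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
  invisible(TRUE)
}
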