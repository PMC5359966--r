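# Independent brute-force oracles, deliberately implemented with different
# algorithms/data structures than the package internals.

# all placements of `read` on each entry with Hamming distance <= max_mm;
# N never matches anything, and a placement covering an N in the entry is
# rejected outright
oracle_hits <- function(entries, read, max_mm) {
  rq <- strsplit(read, "")[[1]]
  out <- list()
  for (i in seq_len(nrow(entries))) {
    sv <- strsplit(toupper(entries$seq[i]), "")[[1]]
    L <- length(sv); n <- length(rq)
    if (n > L || n == 0) next
    for (p in 0:(L - n)) {
      win <- sv[(p + 1):(p + n)]
      if (any(!win %in% c("A", "C", "G", "T"))) next
      mm <- sum(win != rq | !rq %in% c("A", "C", "G", "T"))
      if (mm <= max_mm) {
        out[[length(out) + 1L]] <- data.frame(
          entry_id = entries$entry_id[i], start = p, mismatches = mm,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(entry_id = character(0), start = integer(0),
                      mismatches = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

oracle_min_stratum <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  hits[hits$mismatches == min(hits$mismatches), , drop = FALSE]
}

# connected components of the mature overlap graph by transitive closure of
# the boolean adjacency matrix
oracle_clusters <- function(occurrences) {
  ids <- sort(unique(occurrences$mature_id))
  n <- length(ids)
  adj <- diag(TRUE, n)
  dimnames(adj) <- list(ids, ids)
  for (hp in unique(occurrences$hairpin_id)) {
    sub <- occurrences[occurrences$hairpin_id == hp, , drop = FALSE]
    if (nrow(sub) < 2) next
    for (i in seq_len(nrow(sub))) for (j in seq_len(nrow(sub))) {
      if (sub$start[i] < sub$end[j] && sub$start[j] < sub$end[i]) {
        adj[sub$mature_id[i], sub$mature_id[j]] <- TRUE
      }
    }
  }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj > 0)) break
    adj <- nxt
  }
  membership <- apply(adj, 1, function(row) min(ids[row]))
  split(names(membership), unname(membership))
}

# leftmost tolerant 3'-anchored adapter match, direct R translation of the
# stated rule (scan starts left to right, prefix window, floor(rate*k) budget)
oracle_trim_pos <- function(read, adapter, rate, min_overlap) {
  L <- nchar(read); A <- nchar(adapter)
  rv <- strsplit(read, "")[[1]]
  av <- strsplit(adapter, "")[[1]]
  for (p in seq_len(max(L - min_overlap + 1, 0))) {
    k <- min(A, L - p + 1)
    if (k < min_overlap) break
    mm <- sum(rv[p:(p + k - 1)] != av[1:k])
    if (mm <= floor(rate * k + 1e-9)) return(p)
  }
  0L
}
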