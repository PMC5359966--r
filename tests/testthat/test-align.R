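test_that("index construction validates input and exact reads yield single perfect hits", {
  expect_error(build_index(character(0)), "empty|named")
  expect_error(build_index(data.frame(entry_id = character(0), seq = character(0))),
               "empty")
  idx <- build_index(c(e1 = "ACGTACGTGGCCAATT", e2 = "TTTTGGGGCCCCAAAA"))
  h <- align_reads("CGTACGTGG", idx, max_mm = 0)
  expect_equal(nrow(h), 1L)
  expect_equal(h$entry_id, "e1")
  expect_equal(c(h$start, h$end, h$mismatches), c(1L, 10L, 0L))
})

test_that("alignment is sense-only: reverse complements are not reported", {
  idx <- build_index(c(e1 = "AAACCCGGGTTTACGTACGT"))
  read <- "CCCGGGTTTACG"
  expect_equal(nrow(align_reads(read, idx, max_mm = 1)), 1L)
  expect_equal(nrow(align_reads(revcomp(read), idx, max_mm = 1)), 0L)
  # diagnostic both-strand mode reports the antisense placement
  both <- align_reads(revcomp(read), idx, max_mm = 1, sense_only = FALSE)
  expect_equal(both$strand, "-")
})

test_that("hit sets equal the brute-force Hamming oracle on random instances", {
  set.seed(23)
  for (i in 1:12) {
    n_entries <- sample(2:8, 1)
    entries <- data.frame(
      entry_id = sprintf("e%02d", seq_len(n_entries)),
      seq = mirtally:::random_dna(n_entries, sample(40:90, n_entries, replace = TRUE)))
    # splice delimiters into some entries, as the extended reference has
    if (i %% 2 == 0) {
      s <- entries$seq[1]
      entries$seq[1] <- paste0(substr(s, 1, 20), "N", substr(s, 21, nchar(s)))
    }
    idx <- build_index(entries)
    mm <- sample(0:2, 1)
    reads <- c(
      vapply(seq_len(6), function(k) {   # reads sampled from the reference
        e <- sample(n_entries, 1)
        L <- nchar(entries$seq[e])
        st <- sample(L - 20, 1)
        r <- toupper(substr(entries$seq[e], st, st + 19))
        if (runif(1) < 0.6) {            # sprinkle substitutions
          p <- sample(20, sample(1:2, 1))
          for (q in p) substr(r, q, q) <- sample(c("A", "C", "G", "T", "N"), 1)
        }
        r
      }, character(1)),
      mirtally:::random_dna(4, 20))      # random reads
    got <- align_reads(reads, idx, max_mm = mm)
    for (ri in seq_along(reads)) {
      want <- oracle_min_stratum(oracle_hits(entries, reads[ri], mm))
      g <- got[got$seq_index == ri, c("entry_id", "start", "mismatches")]
      rownames(g) <- rownames(want) <- NULL
      want <- want[order(want$entry_id, want$start), , drop = FALSE]
      rownames(want) <- NULL
      expect_equal(g, want, info = sprintf("instance %d read %d", i, ri))
    }
  }
})

test_that("no reported placement overlaps a reference delimiter", {
  # read spans the N even though the mismatch budget could absorb it
  idx <- build_index(c(e1 = "ACGTACGTNTTGGCCAA"))
  spanning <- "CGTACGTNTTGG"
  expect_equal(nrow(align_reads(spanning, idx, max_mm = 2)), 0L)
  spanning2 <- "CGTACGTATTGG"  # non-N read across the delimiter
  expect_equal(nrow(align_reads(spanning2, idx, max_mm = 2)), 0L)
  # but each side aligns fine
  expect_equal(align_reads("ACGTACGT", idx, max_mm = 0)$start, 0L)
  expect_equal(align_reads("TTGGCCAA", idx, max_mm = 0)$start, 9L)
})

test_that("cascade annotation assigns the first matching tier and conserves totals", {
  mir <- build_index(c(m1 = "AAACCCGGGTTTAAACCCGGG"))
  mrna <- build_index(c(g1 = "AAACCCGGGTTTAAACCCGGGTTTTTTT",
                        g2 = "CATCATCATCATCATCATCAT"))
  reads <- c("AAACCCGGGTTTAAACC",    # hits miRNA and mRNA -> miRNA
             "CATCATCATCATCATCA",    # mRNA only
             "GTGTGTGTGTGTGTGTG")    # nothing
  ann <- annotate_cascade(reads, mir, mrna_index = mrna)
  expect_equal(as.character(ann$category), c("miRNA", "mRNA", "unaligned"))
  expect_equal(sum(table(ann$category)), length(reads))
  expect_equal(ann$mirna_hits$seq_index, 1L)

  # ambiguous read with equal-mismatch hits in two entries: counted once,
  # attributed to the lexicographically smallest entry, and tallied
  amb <- build_index(c(b = "TTACGTACGTACGTT", a = "GGACGTACGTACGGG"))
  ann2 <- annotate_cascade("ACGTACGTACG", amb)
  expect_equal(nrow(ann2$mirna_hits), 1L)
  expect_equal(ann2$mirna_hits$entry_id, "a")
  expect_equal(ann2$multi_entry_reads, 1L)
})

test_that("remapping invalidates mismatch reads with perfect genomic matches only", {
  mature <- "TAGCTTATCAGACTGATGTTGA"
  hairpin <- paste0("GGGGG", mature, "CCCCC")
  idx <- build_index(c(m1 = hairpin))
  variant <- mature
  substr(variant, 8, 8) <- "G"  # read "a": 1 mismatch to the miRNA
  reads <- c(mature, variant, sub("T", "C", mature))
  ann <- annotate_cascade(reads, idx)
  counts <- matrix(c(5L, 3L, 2L), ncol = 1,
                   dimnames = list(NULL, "S1"))

  # genome carries the variant locus: read "a" invalidated, exact read kept
  genome <- c(paste0("TTTT", variant, "AAAA"))
  res <- remap_invalidate(ann$mirna_hits, reads, genome, counts)
  v <- setNames(res$mirna_hits$valid, reads[res$mirna_hits$seq_index])
  expect_false(v[[variant]])
  expect_true(v[[mature]])
  expect_equal(res$stats$n_candidates, 2L)
  expect_equal(res$stats$n_invalidated, 1L)
  expect_equal(res$stats$rate_unique_pct, 50)
  expect_equal(res$stats$rate_total_pct, 100 * 3 / 5)

  # reverse-strand genomic occurrence also invalidates
  genome_rc <- revcomp(genome)
  res_rc <- remap_invalidate(ann$mirna_hits, reads, genome_rc, counts)
  expect_false(res_rc$mirna_hits$valid[res_rc$mirna_hits$seq_index ==
                                         which(reads == variant)])

  # no genome: everything stays valid; invalidation is monotone
  res0 <- remap_invalidate(ann$mirna_hits, reads, NULL)
  expect_true(all(res0$mirna_hits$valid))
  expect_true(all(res$mirna_hits$valid <= res0$mirna_hits$valid))
})
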