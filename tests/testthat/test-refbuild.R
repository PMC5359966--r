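test_that("FASTA parsing converts RNA to DNA, filters by species, and validates records", {
  f <- write_tmp_fasta(c("x", "hsa-a", "mmu-b"), c("UGAGG", "acgu", "GGUU"))
  rec <- read_fasta_records(f)
  expect_equal(rec$seq, c("TGAGG", "ACGT", "GGTT"))
  expect_equal(read_fasta_records(f, species = "hsa-")$id, "hsa-a")

  empty <- tempfile(fileext = ".fa")
  file.create(empty)
  expect_equal(nrow(read_fasta_records(empty)), 0L)

  dup <- write_tmp_fasta(c("a", "a"), c("ACGT", "GGGG"))
  expect_error(read_fasta_records(dup), "duplicate")

  bad <- write_tmp_fasta("z", "ACXGT")
  expect_error(read_fasta_records(bad), "outside")
})

test_that("identical sequences collapse into representative groups partitioning the input", {
  rec <- data.frame(id = c("b", "a", "c"), seq = c("ACGT", "ACGT", "GGGG"))
  g <- dedup_sequences(rec)
  expect_equal(g$rep_id, c("a", "c"))
  expect_equal(g$member_ids, c("a,b", "c"))
  expect_equal(sum(g$n_members), nrow(rec))

  # property: random records with planted duplicates still partition the input
  set.seed(42)
  for (i in 1:10) {
    n <- sample(3:20, 1)
    pool <- mirtally:::random_dna(sample(2:6, 1), 8)
    rec <- data.frame(id = sprintf("id%02d", seq_len(n)),
                      seq = sample(pool, n, replace = TRUE))
    g <- dedup_sequences(rec)
    expect_equal(sum(g$n_members), n)
    expect_setequal(unlist(strsplit(g$member_ids, ",")), rec$id)
    expect_equal(g$rep_id,
                 vapply(strsplit(g$member_ids, ","), min, character(1)))
  }
})

test_that("mature-to-hairpin mapping reports every sense occurrence and flags orphans", {
  matures <- dedup_sequences(data.frame(
    id = c("m1", "m2", "m3"),
    seq = c("ACG", "TTTTTTTT", revcomp("TTACGTT"))))
  hairpins <- dedup_sequences(data.frame(id = "h1", seq = "TTACGTTACG"))
  expect_warning(occ <- map_matures_to_hairpins(matures, hairpins), "orphan|excluded")
  m1 <- occ[occ$mature_id == "m1", ]
  expect_equal(m1$start, c(2L, 7L))  # both occurrences within one hairpin
  expect_equal(m1$end, c(5L, 10L))
  # m3 matches only the antisense strand, so it is an orphan
  expect_setequal(attr(occ, "orphans"), c("m2", "m3"))

  # identical mature on two hairpins: one group, two occurrences
  mat2 <- dedup_sequences(data.frame(id = c("p", "q"), seq = c("ACGTAC", "ACGTAC")))
  hp2 <- dedup_sequences(data.frame(id = c("h1", "h2"),
                                    seq = c("GGACGTACGG", "TTTACGTACT")))
  occ2 <- map_matures_to_hairpins(mat2, hp2)
  expect_equal(nrow(occ2), 2L)
  expect_equal(unique(occ2$mature_id), "p")
})

test_that("overlap clustering equals brute-force connected components on random instances", {
  set.seed(7)
  for (i in 1:25) {
    n_mat <- sample(2:12, 1)
    n_hp <- sample(1:4, 1)
    occ <- do.call(rbind, lapply(seq_len(n_mat), function(m) {
      k <- sample(1:2, 1)
      data.frame(mature_id = sprintf("m%02d", m),
                 hairpin_id = sprintf("h%d", sample(n_hp, k, replace = TRUE)),
                 start = sample(0:40, k, replace = TRUE))
    }))
    occ$end <- occ$start + sample(15:25, nrow(occ), replace = TRUE)
    got <- cluster_matures(occ)
    want <- oracle_clusters(occ)
    got_parts <- unname(lapply(split(got$mature_id, got$cluster_id), sort))
    want_parts <- unname(lapply(want, sort))
    expect_setequal(got_parts, want_parts)
    # cluster id is the smallest member id
    expect_true(all(mapply(function(id, ms) id == min(ms),
                           names(split(got$mature_id, got$cluster_id)),
                           split(got$mature_id, got$cluster_id))))
  }
})

test_that("flank extension clips at hairpin boundaries and case-encodes the mature", {
  seg <- extend_mature("AAAACGTTTT", start = 3, end = 7, extension = 2)
  expect_equal(seg$segment_seq, "aaACGTtt")
  expect_equal(c(seg$flank5, seg$flank3), c(2, 2))

  seg0 <- extend_mature("ACGTGGGG", start = 0, end = 4, extension = 4)
  expect_equal(c(seg0$flank5, seg0$flank3), c(0, 4))
  expect_equal(seg0$segment_seq, "ACGTgggg")

  # uppercase region reconstructs the mature exactly
  hp <- mirtally:::random_dna(1, 60)
  seg2 <- extend_mature(hp, 10, 32, 4)
  expect_equal(gsub("[a-z]", "", seg2$segment_seq), substr(hp, 11, 32))
})

test_that("assembled entries obey the delimiter grammar and are deterministic", {
  exp <- synth_experiment(tiny_params(reads_per_sample = 0,
                                      decoy_reads_per_sample = 0),
                          with_genome = FALSE)
  ref <- build_ref_from_synth(exp)

  # duplicate mature (two precursors) -> one entry, two segments, one single N
  dup_entry <- ref$entries$seq[ref$entries$entry_id == "syn-miR-001-5p"]
  runs <- regmatches(dup_entry, gregexpr("N+", dup_entry))[[1]]
  expect_equal(runs, "N")
  expect_equal(sum(ref$annotation$entry_id == "syn-miR-001-5p"), 2L)

  # single mature, single hairpin -> zero N
  solo <- ref$entries$seq[ref$entries$entry_id == "syn-miR-004-5p"]
  expect_false(grepl("N", solo))

  # delimiter grammar across all entries: N runs of length 1 or 2 only,
  # and segments = runs + 1
  for (i in seq_len(nrow(ref$entries))) {
    s <- ref$entries$seq[i]
    runs <- regmatches(s, gregexpr("N+", s))[[1]]
    expect_true(all(nchar(runs) %in% 1:2))
    expect_equal(sum(ref$annotation$entry_id == ref$entries$entry_id[i]),
                 length(runs) + 1L)
  }

  # uppercase region of every segment equals its mature group's sequence
  mat_seq <- setNames(ref$mature_groups$seq, ref$mature_groups$rep_id)
  ann <- ref$annotation
  ent_seq <- setNames(ref$entries$seq, ref$entries$entry_id)
  for (i in seq_len(nrow(ann))) {
    up <- unname(substr(ent_seq[ann$entry_id[i]], ann$mature_start[i] + 1L,
                        ann$mature_end[i]))
    expect_equal(up, unname(mat_seq[ann$mature_id[i]]))
  }

  # per-cluster mode: the 3-mature overlap cluster joins different matures by NN
  refc <- build_ref_from_synth(exp, mode = "per-cluster")
  trio <- refc$entries$seq[refc$entries$entry_id == "syn-miR-003a"]
  runs <- regmatches(trio, gregexpr("N+", trio))[[1]]
  expect_equal(runs, c("NN", "NN"))

  # determinism: rebuilding and rewriting yields byte-identical files
  ref2 <- build_ref_from_synth(exp)
  expect_identical(ref$entries, ref2$entries)
  d1 <- tempfile(); d2 <- tempfile()
  write_reference(ref, d1); write_reference(ref2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})
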