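test_that("noise filter removes exactly the rows predicted by the two predicates", {
  m <- rbind(sporadic = c(0L, 0L, 0L, 0L, 9L),   # zero fraction 0.8 > 0.6
             low = c(1L, 1L, 1L, 1L, 1L),        # mean 1 < 2, zero fraction 0
             solid = c(5L, 5L, 5L, 5L, 5L))
  or_res <- suppressMessages(filter_noise(m, mode = "OR"))
  expect_equal(or_res$keep, c(sporadic = FALSE, low = FALSE, solid = TRUE))
  and_res <- suppressMessages(filter_noise(m, mode = "AND"))
  expect_equal(and_res$keep, c(sporadic = FALSE, low = TRUE, solid = TRUE))

  # property: random matrices agree with direct predicate evaluation
  set.seed(9)
  for (i in 1:20) {
    n <- sample(2:12, 1); k <- sample(1:40, 1)
    mm <- matrix(rpois(n * k, sample(c(0.3, 1, 4), 1)), nrow = k)
    zf <- rowMeans(mm == 0); mu <- rowMeans(mm)
    got_or <- suppressMessages(filter_noise(mm, 0.60, 2, "OR"))$removed
    expect_equal(got_or, (zf > 0.60) | (mu < 2))
    got_and <- suppressMessages(filter_noise(mm, 0.60, 2, "AND"))$removed
    expect_equal(got_and, (zf > 0.60) & (mu < 2))
  }
})

test_that("miRNA counting fills standard and mismatch-only companions correctly", {
  hits <- data.frame(seq_index = c(1L, 2L, 3L),
                     entry_id = c("mA", "mA", "mB"),
                     start = 0L, end = 22L,
                     mismatches = c(0L, 1L, 0L),
                     valid = c(TRUE, TRUE, TRUE))
  counts <- matrix(c(7L, 4L, 2L,
                     0L, 1L, 3L), ncol = 2,
                   dimnames = list(NULL, c("S1", "S2")))
  tabs <- count_mirna(hits, counts)
  expect_equal(tabs$standard["mA", ], c(S1 = 11L, S2 = 1L))
  expect_equal(tabs$standard["mB", ], c(S1 = 2L, S2 = 3L))
  # the 1-mismatch read (kept after remap) contributes to both tables
  expect_equal(tabs$mismatch_only["mA", ], c(S1 = 4L, S2 = 1L))
  expect_equal(tabs$mismatch_only["mB", ], c(S1 = 0L, S2 = 0L))
  # standard - companion equals a direct perfect-only recount
  perfect <- count_mirna(hits[hits$mismatches == 0, ], counts)$standard
  expect_equal(tabs$standard - tabs$mismatch_only,
               perfect[rownames(tabs$standard), , drop = FALSE])
  # invalidated hits never contribute
  hits$valid[2] <- FALSE
  expect_equal(count_mirna(hits, counts)$standard["mA", ], c(S1 = 7L, S2 = 0L))
  # the noise filter mask removes reads before counting; with a fixed row
  # universe the filtered entry shows an all-zero row
  keep <- c(TRUE, TRUE, FALSE)
  hits$valid[2] <- TRUE
  filtered <- count_mirna(hits, counts, keep = keep)
  expect_false("mB" %in% rownames(filtered$standard))
  fixed <- count_mirna(hits, counts, keep = keep, entries = c("mA", "mB"))
  expect_equal(fixed$standard["mB", ], c(S1 = 0L, S2 = 0L))
})

test_that("end offsets follow the segment arithmetic and sign conventions", {
  # hairpin with mature at [10, 32), extension 4 -> segment seg_start 0
  ann <- data.frame(entry_id = "m", segment_index = 1L, hairpin_id = "h",
                    mature_id = "m", member_ids = "m", seg_start = 0L,
                    mature_start = 4L, mature_end = 26L,
                    flank5 = 4L, flank3 = 4L)
  mk_hit <- function(start, end) data.frame(
    seq_index = 1L, entry_id = "m", start = start, end = end,
    mismatches = 0L, valid = TRUE)
  canonical <- compute_offsets(mk_hit(4L, 26L), ann)
  expect_equal(c(canonical$offset5, canonical$offset3), c(0L, 0L))
  # dominant isoform 2 nt longer at the 3' end
  longer3 <- compute_offsets(mk_hit(4L, 28L), ann)
  expect_equal(c(longer3$offset5, longer3$offset3), c(0L, 2L))
  # trimmed 1 nt at 5', extended 3 nt at 3'
  both <- compute_offsets(mk_hit(5L, 29L), ann)
  expect_equal(c(both$offset5, both$offset3), c(1L, 3L))
  # read starting in the 5' flank has a negative 5' offset
  up <- compute_offsets(mk_hit(3L, 26L), ann)
  expect_equal(up$offset5, -1L)
})

test_that("isomiR rows aggregate by offset key and conserve miRNA totals", {
  # two distinct sequences with identical (entry, offsets) collapse to one row
  hits <- data.frame(seq_index = 1:3,
                     entry_id = c("m", "m", "m"),
                     start = c(4L, 4L, 5L), end = c(26L, 26L, 27L),
                     mismatches = c(0L, 1L, 0L),
                     valid = TRUE,
                     segment_index = 1L,
                     offset5 = c(0L, 0L, 1L), offset3 = c(0L, 0L, 1L))
  counts <- matrix(c(5L, 2L, 1L), ncol = 1, dimnames = list(NULL, "S1"))
  iso <- count_isomir(hits, counts)
  expect_equal(nrow(iso$standard), 2L)
  expect_equal(iso$standard["m|0|0", "S1"], 7L)
  expect_equal(iso$mismatch_only["m|0|0", "S1"], 2L)
  # per entry, isomiR rows sum to the miRNA table cell
  mir <- count_mirna(hits, counts)
  expect_equal(sum(iso$standard[iso$keys$entry_id == "m", ]),
               sum(mir$standard["m", ]))
})

test_that("RPM columns scale to one million under the miRNA-mapped denominator", {
  m <- matrix(c(1L, 1L, 3L, 9L), ncol = 2, dimnames = list(c("a", "b"), c("S1", "S2")))
  rpm <- rpm_normalize(m)
  expect_equal(rpm[, "S1"], c(a = 5e5, b = 5e5))
  expect_equal(unname(colSums(rpm)), c(1e6, 1e6))
  # library-size denominator against hand computation
  rpm2 <- rpm_normalize(m, denominators = c(S1 = 10, S2 = 24))
  expect_equal(rpm2["a", "S2"], 3 * 1e6 / 24)
  # zero denominator yields NA with a warning
  expect_warning(rpm3 <- rpm_normalize(m, denominators = c(S1 = 2, S2 = 0)),
                 "zero denominator")
  expect_true(all(is.na(rpm3[, "S2"])))
  expect_false(anyNA(rpm3[, "S1"]))
})
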