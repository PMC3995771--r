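test_that("window variants tally concrete L-mers and exclude gaps", {
  db <- make_db(c("AA", "AA", "AA", "AG", "AG", "CC"))
  wv <- window_variants(db, 1, 2)
  expect_identical(wv$variants, c(AA = 3L, AG = 2L, CC = 1L))
  expect_identical(wv$excluded_count, 0L)
  # a gap or ambiguity code inside the window excludes the sequence
  db2 <- make_db(c("AA", "A-", "AN"))
  wv2 <- window_variants(db2, 1, 2)
  expect_identical(wv2$variants, c(AA = 1L))
  expect_identical(wv2$excluded_count, 2L)
  expect_identical(sum(wv2$variants) + wv2$excluded_count, wv2$n_total)
  expect_error(window_variants(db, 2, 2), "out of alignment range")
})

test_that("best oligo maximizes coverage within the degeneracy bound", {
  db <- make_db(c("AA", "AA", "AA", "AG", "AG", "CC"))
  wv <- window_variants(db, 1, 2)
  bo <- best_degenerate_oligo(wv, 2)
  expect_identical(bo$sequence, "AR")
  expect_identical(bo$matched_count, 5L)
  # single variant
  bo2 <- best_degenerate_oligo(window_variants(make_db(rep("AA", 3)), 1, 2),
                               100)
  expect_identical(bo2$sequence, "AA")
  expect_identical(bo2$matched_count, 3L)
  # tie at max_degeneracy 1 broken lexicographically
  db3 <- make_db(c(rep("AA", 3), rep("CC", 3)))
  bo3 <- best_degenerate_oligo(window_variants(db3, 1, 2), 1)
  expect_identical(bo3$sequence, "AA")
  expect_identical(bo3$matched_count, 3L)
  # empty variant table -> no-oligo signal
  expect_null(best_degenerate_oligo(window_variants(make_db(c("A-", "-A")),
                                                    1, 2), 4))
})

test_that("matched count never drops when the degeneracy bound grows", {
  for (seed in 1:10) {
    db <- random_alignment(15, 6, gap_prob = 0, seed = 20 + seed)
    wv <- window_variants(db, 1, 4)
    scores <- vapply(c(1, 2, 4, 8, 12, 24), function(d) {
      best_degenerate_oligo(wv, d)$matched_count
    }, integer(1))
    expect_true(all(diff(scores) >= 0))
    degs <- vapply(c(1, 2, 4, 8, 12, 24), function(d) {
      bo <- best_degenerate_oligo(wv, d)
      expect_lte(bo$degeneracy, d)
      bo$degeneracy
    }, integer(1))
  }
})

test_that("search equals the exhaustive subset-enumeration oracle", {
  set.seed(99)
  n_checked <- 0
  while (n_checked < 60) {
    L <- sample(2:6, 1)
    db <- random_alignment(sample(5:12, 1), L, gap_prob = 0, seed = NULL)
    wv <- window_variants(db, 1, L)
    if (length(wv$variants) > 8) next
    maxd <- sample(c(1, 2, 4, 8, 12), 1)
    bo <- best_degenerate_oligo(wv, maxd)
    expect_identical(bo$matched_count,
                     as.integer(oracle_best_score(wv$variants, maxd)))
    expect_lte(bo$degeneracy, maxd)
    n_checked <- n_checked + 1
  }
})

test_that("the greedy large-table path still dominates the top variant", {
  set.seed(123)
  db <- random_alignment(80, 5, gap_prob = 0, seed = NULL)
  wv <- window_variants(db, 1, 5)
  # force the greedy path regardless of table size
  bo <- best_degenerate_oligo(wv, 12, exact_max_variants = 0L)
  expect_gte(bo$matched_count, max(wv$variants))
  expect_lte(bo$degeneracy, 12)
})

test_that("alignment scan profiles every window", {
  db <- make_db(rep("ACGTACGT", 5))
  tr <- trim_alignment(db, 0.9)
  scan <- scan_alignment(tr, length = 4, max_degeneracy = 4)
  expect_identical(nrow(scan), 5L)
  expect_true(all(scan$fraction == 1.0))
  expect_true(all(scan$matched_count == 5L))
  # max_degeneracy 1: each window's oligo is its most frequent variant
  db2 <- random_alignment(10, 8, gap_prob = 0, seed = 5)
  tr2 <- trim_alignment(db2, 0.5)
  scan2 <- scan_alignment(tr2, length = 3, max_degeneracy = 1)
  for (i in seq_len(nrow(scan2))) {
    wv <- window_variants(tr2, scan2$window_start[i], 3)
    top <- max(wv$variants)
    expect_identical(scan2$matched_count[i],
                     as.integer(oracle_best_score(wv$variants, 1)))
    expect_gte(scan2$matched_count[i], top)
    expect_identical(primer_degeneracy(scan2$oligo[i]), 1L)
  }
})

test_that("scan maps window starts to reference coordinates", {
  db <- make_db(c("AACGGT", "AA-GGT", "AACGGT"), ids = c("ref", "b", "c"))
  tr <- trim_alignment(db, 0.9)
  rm <- build_reference_map(db, "ref")
  scan <- scan_alignment(tr, length = 2, max_degeneracy = 4,
                         reference_map = rm)
  expect_true("reference_position" %in% names(scan))
  expect_identical(scan$reference_position[1], 1L)
})
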