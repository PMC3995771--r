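test_that("e-value combination is the mean of log10 e-values", {
  expect_equal(combine_evalues(c(1e-10, 1e-4)), -7.0)
  expect_equal(combine_evalues(1e-5), -5.0)
  set.seed(1)
  ev <- 10^(-runif(6, 1, 30))
  expect_equal(combine_evalues(ev), combine_evalues(sample(ev)))
  expect_error(combine_evalues(c(1e-3, 0)), "positive")
})

test_that("query sampling is reproducible and honors eligibility filters", {
  fx <- small_benchmark_fixture()
  q1 <- sample_queries(fx$db, 5, seed = 42)
  q2 <- sample_queries(fx$db, 5, seed = 42)
  expect_identical(q1$id, q2$id)
  # n = pool size returns the whole pool
  qall <- sample_queries(fx$db, length(fx$db$id), seed = 1)
  expect_setequal(qall$id, fx$db$id)
  expect_error(sample_queries(fx$db, length(fx$db$id) + 1), "pool")
  # a record lacking one primer's site is ineligible
  db <- make_db(c("ACGTACTTTTGGCATGTTTT", "TTTTTCTTTTGGCATGTTTT"),
                taxonomy = list(c("f1", "g1", "s1"), c("f1", "g1", "s2")))
  q <- sample_queries(db, 1, require_full_taxonomy = TRUE,
                      require_matched_by = c("ACGTAC", "GGCATG"), seed = 1)
  expect_identical(q$id, "s1")
})

test_that("best-hit search finds exact duplicates and honors exclusion", {
  set.seed(5)
  base <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  other <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  seqs <- c(q = base, dup = base, far = other)
  idx <- build_search_index(seqs)
  read <- substr(base, 50, 299)
  hit <- search_best_hit(read, idx, exclude = "q")
  expect_identical(hit$subject_id, "dup")
  expect_equal(hit$identity, 1.0)
  # only the query itself matches and it is excluded -> no hit
  seqs2 <- c(q = base, far = other)
  idx2 <- build_search_index(seqs2)
  expect_null(search_best_hit(read, idx2, exclude = "q"))
  # reverse-complement-oriented reads are still found
  hit_rc <- search_best_hit(reverse_complement(read), idx, exclude = "q")
  expect_identical(hit_rc$subject_id, "dup")
})

test_that("prefiltered search equals the exhaustive search", {
  fx <- small_benchmark_fixture()
  idx <- build_search_index(fx$db)
  amp <- simulate_amplicons(fx$db, fx$fwd, fx$rev, read_length = 150,
                            paired = TRUE)
  for (i in c(1, 5, 9, 13)) {
    reads <- c(amp$fwd_read[i], amp$rev_read[i])
    h1 <- search_best_hit(reads, idx, exclude = amp$record_id[i],
                          prefilter = TRUE)
    h2 <- search_best_hit(reads, idx, exclude = amp$record_id[i],
                          prefilter = FALSE)
    expect_identical(h1$subject_id, h2$subject_id)
    expect_equal(h1$combined_score, h2$combined_score)
  }
})

test_that("agreement categories follow the rank comparison rules", {
  q <- c("k1", "p1", "c1", "o1", "f1", "g1", "s1")
  expect_identical(assess_agreement(q, q), "species")
  expect_identical(assess_agreement(q, replace(q, 7, "s2")), "genus")
  expect_identical(assess_agreement(q, replace(q, 6:7, c("g2", "s9"))),
                   "above_genus")
  expect_identical(assess_agreement(q, replace(q, 5:7, c("f2", "g2", "s2"))),
                   "misassigned")
  # hit annotated only above family depth is excluded
  expect_identical(assess_agreement(q, q[1:4]), "excluded_hit_unannotated")
  # hit annotated exactly to family and agreeing there counts above genus
  expect_identical(assess_agreement(q, q[1:5]), "above_genus")
})

test_that("gap-aware distance follows the one-gap counting rules", {
  expect_equal(full_length_distance("ACGT", "ACGT"), 0.0)
  expect_equal(full_length_distance("AC-GT", "ACCGT"), 0.2)
  expect_equal(full_length_distance("--CGT", "AACGT"), 0.0)
  # a 3-column gap run is one difference and one unit
  expect_equal(full_length_distance("AC---GT", "ACTTTGT"), 1 / 5)
  # both-gap columns are skipped: one gap run + one mismatch over 6 units
  expect_equal(full_length_distance("AC--AGT", "ACT-TGT"), 2 / 6)
  expect_error(full_length_distance("ACGT", "ACG"), "equal gapped length")
  expect_warning(d <- full_length_distance("A---", "-CCC"), "undefined")
  expect_true(is.na(d))
})

test_that("gap-aware distance is symmetric with zero self-distance", {
  set.seed(8)
  for (i in 1:15) {
    n <- 40
    a <- paste(sample(c("A", "C", "G", "T", "-"), n, TRUE,
                      prob = c(0.22, 0.22, 0.22, 0.22, 0.12)), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T", "-"), n, TRUE,
                      prob = c(0.22, 0.22, 0.22, 0.22, 0.12)), collapse = "")
    expect_equal(suppressWarnings(full_length_distance(a, a)), 0)
    expect_equal(suppressWarnings(full_length_distance(a, b)),
                 suppressWarnings(full_length_distance(b, a)))
    d <- suppressWarnings(full_length_distance(a, b))
    if (!is.na(d)) expect_true(d >= 0 && d <= 1)
  }
})

test_that("the benchmark pipeline partitions queries across categories", {
  fx <- small_benchmark_fixture()
  res <- run_benchmark(fx$db, fx$fwd, fx$rev, read_length = 150,
                       paired = TRUE, n_queries = 8, seed = 2)
  expect_identical(nrow(res$assignments), res$n_amplified)
  expect_identical(res$n_assessed + res$n_excluded + res$n_no_hit,
                   res$n_amplified)
  fr <- res$accuracy$fraction
  if (res$n_assessed > 0) expect_equal(sum(fr), 1.0)
  # stricter identity threshold can only lose assignments
  res95 <- run_benchmark(fx$db, fx$fwd, fx$rev, read_length = 150,
                         paired = TRUE, n_queries = 8, seed = 2,
                         min_identity = 0.95)
  expect_gte(res95$n_assessed + res95$n_excluded, res$n_assessed +
               res$n_excluded)
  # same seed and inputs reproduce the identical result
  res_b <- run_benchmark(fx$db, fx$fwd, fx$rev, read_length = 150,
                         paired = TRUE, n_queries = 8, seed = 2)
  expect_identical(res$assignments, res_b$assignments)
  expect_identical(res$distances, res_b$distances)
})
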