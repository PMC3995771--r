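# hand-constructed template with a forward site and a reverse footprint at
# exact positions: amplicon length = rev_end - fwd_start + 1
build_template <- function(amplicon_length, lead = 10, tail = 10,
                           fwd = "ACGTAC", rev_site = "GGCATG", seed = 1) {
  set.seed(seed)
  inner <- amplicon_length - nchar(fwd) - nchar(rev_site)
  stopifnot(inner >= 0)
  mid <- paste(sample(c("A", "C", "T"), inner, replace = TRUE),
               collapse = "")  # no G: primers cannot re-occur
  paste0(paste(rep("T", lead), collapse = ""), fwd, mid, rev_site,
         paste(rep("T", tail), collapse = ""))
}

test_that("paired reads merge when they overlap and concatenate when not", {
  fwd <- "ACGTAC"
  rev <- reverse_complement("GGCATG")
  # amplicon 200, 2x150: overlap 100, fused = full amplicon
  t200 <- c(r1 = build_template(200))
  a <- simulate_amplicons(t200, fwd, rev, read_length = 150, paired = TRUE)
  expect_identical(a$amplicon_length, 200L)
  expect_identical(nchar(a$fused), 200L)
  expect_identical(a$fused, substr(t200[[1]], 11, 210))  # the true template
  # amplicon 400, 2x150: no overlap, fused = 300-char concatenation
  t400 <- c(r1 = build_template(400))
  b <- simulate_amplicons(t400, fwd, rev, read_length = 150, paired = TRUE)
  expect_identical(b$amplicon_length, 400L)
  expect_identical(nchar(b$fused), 300L)
  expect_identical(substr(b$fused, 1, 150), b$fwd_read)
  expect_identical(substr(b$fused, 151, 300), b$rev_read)
  # amplicon 200, single 400: one read truncated at the amplicon end
  s <- simulate_amplicons(t200, fwd, rev, read_length = 400, paired = FALSE)
  expect_identical(nchar(s$fused), 200L)
  expect_true(is.na(s$rev_read))
})

test_that("reads start at the forward site and include primer bases", {
  fwd <- "ACGTAC"
  rev <- reverse_complement("GGCATG")
  t <- c(r1 = build_template(300))
  a <- simulate_amplicons(t, fwd, rev, read_length = 100, paired = TRUE)
  expect_identical(substr(a$fwd_read, 1, 6), "ACGTAC")
  # reverse read is reverse-complement oriented: starts with RC(footprint end)
  expect_identical(substr(a$rev_read, 1, 6), reverse_complement("GGCATG"))
})

test_that("records lacking either site are skipped with a reason", {
  fwd <- "ACGTAC"
  rev <- reverse_complement("GGCATG")
  seqs <- c(ok = build_template(150),
            nofwd = gsub("ACGTAC", "TTTTTT", build_template(150)),
            norev = gsub("GGCATG", "TTTTTT", build_template(150)))
  a <- simulate_amplicons(seqs, fwd, rev, read_length = 100, paired = TRUE)
  expect_identical(a$record_id, "ok")
  sk <- attr(a, "skipped")
  expect_setequal(sk$record_id, c("nofwd", "norev"))
  expect_identical(sk$reason[sk$record_id == "nofwd"], "no_forward_site")
})

test_that("unique ratio counts distinct amplicons over distinct regions", {
  # all identical records -> ratio 1
  fwd <- "ACGTAC"
  rev <- reverse_complement("GGCATG")
  tmpl <- build_template(120, lead = 5, tail = 15)
  db_same <- make_db(rep(tmpl, 4))
  amp <- simulate_amplicons(db_same, fwd, rev, read_length = 200,
                            paired = FALSE)
  expect_equal(as.numeric(unique_ratio(amp, db_same, "s1",
                                       c(1, nchar(tmpl)))), 1.0)
  # 3 distinct full-length records, 2 sharing the amplicon region -> 2/3
  t1 <- tmpl
  t2 <- paste0(substr(tmpl, 1, nchar(tmpl) - 1), "G")   # differs in tail only
  chars <- strsplit(tmpl, "")[[1]]
  chars[40] <- if (chars[40] == "A") "C" else "A"       # differs inside
  t3 <- paste(chars, collapse = "")
  db3 <- make_db(c(t1, t2, t3))
  amp3 <- simulate_amplicons(db3, fwd, rev, read_length = 200,
                             paired = FALSE)
  ur <- unique_ratio(amp3, db3, "s1", c(1, nchar(tmpl)))
  expect_equal(as.numeric(ur), 2 / 3)
  cnt <- attr(ur, "counts")
  expect_identical(unname(cnt["unique_amplicons"]), 2L)
  expect_identical(unname(cnt["unique_fulllength"]), 3L)
})

test_that("unique ratio never drops as reads get longer", {
  fx <- small_benchmark_fixture()
  region <- c(1, 450)
  ratios <- vapply(c(100, 150, 250, 400), function(rl) {
    amp <- simulate_amplicons(fx$db, fx$fwd, fx$rev, read_length = rl,
                              paired = TRUE)
    as.numeric(unique_ratio(amp, fx$db, fx$db$id[1], region))
  }, numeric(1))
  expect_true(all(diff(ratios) >= 0))
})
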