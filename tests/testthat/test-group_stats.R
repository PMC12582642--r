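test_that("exact rank-sum p-values match full enumeration over all small designs", {
  # canonical example: complete separation of 3 vs 3
  r <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1, tolerance = 1e-12)
  expect_identical(r$method, "exact")

  # every (n_x, n_y) with combined n <= 12, several tie-free draws each
  set.seed(12)
  for (nx in 1:6) for (ny in nx:(12 - nx)) {
    for (rep in 1:3) {
      v <- sample(1000, nx + ny)  # distinct => no ties
      x <- v[seq_len(nx)]; y <- v[-seq_len(nx)]
      got <- rank_sum_test(x, y)
      want <- oracle_rank_sum_exact(x, y)
      expect_identical(got$method, "exact")
      expect_equal(got$U, want$U)
      expect_equal(got$p, want$p, tolerance = 1e-12)
    }
  }
})

test_that("swap symmetry, tie handling, and the degenerate case behave", {
  set.seed(3)
  x <- stats::rnorm(7); y <- stats::rnorm(5, 1)
  a <- rank_sum_test(x, y); b <- rank_sum_test(y, x)
  expect_equal(a$U, length(x) * length(y) - b$U)
  expect_equal(a$p, b$p, tolerance = 1e-12)

  # all pooled values identical: vacuous comparison, p = 1
  d <- rank_sum_test(c(5, 5), c(5, 5))
  expect_equal(d$p, 1)
  expect_identical(d$method, "degenerate")

  # ties force the tie-corrected normal approximation
  t1 <- rank_sum_test(c(1, 2, 2, 3), c(2, 3, 3, 4))
  expect_identical(t1$method, "normal_approx")
  expect_true(t1$p > 0 && t1$p <= 1)

  expect_error(rank_sum_test(numeric(0), 1:3), "non-empty")
  expect_error(rank_sum_test(c(1, NA), 1:3), "finite")
})

test_that("normal approximation tracks the exact p on random small samples", {
  set.seed(31)
  worst <- 0
  for (i in 1:50) {
    nx <- sample(5:10, 1); ny <- sample(5:10, 1)
    v <- sample(10000, nx + ny)
    x <- v[seq_len(nx)]; y <- v[-seq_len(nx)]
    p_exact <- oracle_rank_sum_exact(x, y)$p
    p_norm <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                                  correct = TRUE))$p.value
    worst <- max(worst, abs(p_norm - p_exact))
  }
  expect_lt(worst, 0.02)
})

test_that("p-values are invariant under strictly monotone transforms", {
  set.seed(14)
  x <- stats::rnorm(9); y <- stats::rnorm(11, 0.8)
  base <- rank_sum_test(x, y)
  for (f in list(function(v) exp(v), function(v) v^3,
                 function(v) 5 * v - 2)) {
    tr <- rank_sum_test(f(x), f(y))
    expect_equal(tr$p, base$p, tolerance = 1e-12)
    expect_equal(tr$U, base$U)
  }
})

test_that("cohort comparison drops unusable records and tiers correctly", {
  labels <- data.frame(patient = sprintf("P%02d", 1:12),
                       tilt_deg = c(rep(0, 8), rep(40, 4)),
                       label = c(rep("normal", 8), rep("abnormal", 4)),
                       stringsAsFactors = FALSE)
  st <- structure(list(lower_threshold_deg = -5, upper_threshold_deg = 20,
                       lower_pct = 12, upper_pct = 88, labels = labels),
                  class = "cohort_stratification")
  rec <- data.frame(patient = labels$patient, structure = "parotid_l",
                    source = "v1",
                    sdsc = c(0.9, 0.91, 0.92, 0.93, 0.9, 0.94, 0.92, 0.91,
                             0.5, 0.55, 0.52, 0.58),
                    status = "ok", stringsAsFactors = FALSE)
  out <- compare_cohorts(rec, st, "sdsc")
  expect_equal(out$n_normal, 8)
  expect_equal(out$n_abnormal, 4)
  expect_lt(out$median_diff, 0)
  expect_lt(out$p, 0.01)
  expect_identical(out$tier, "**")

  # identical distributions: p = 1, tier ns
  rec2 <- rec
  rec2$sdsc <- 0.9
  out2 <- compare_cohorts(rec2, st, "sdsc")
  expect_equal(out2$p, 1)
  expect_identical(out2$tier, "ns")

  # missing + excluded records are dropped before testing
  rec3 <- rec
  rec3$status[1] <- "missing_empty_mask"
  rec3$excluded <- FALSE
  rec3$excluded[2] <- TRUE
  out3 <- compare_cohorts(rec3, st, "sdsc")
  expect_equal(out3$n_normal, 6)

  # a group shrunk below 2 usable records becomes untestable
  rec4 <- rec
  rec4$status[9:11] <- "missing_empty_mask"
  out4 <- compare_cohorts(rec4, st, "sdsc")
  expect_identical(out4$tier, "untestable")
  expect_true(is.na(out4$p))

  # labels must cover all records
  rec5 <- rbind(rec, data.frame(patient = "P99", structure = "parotid_l",
                                source = "v1", sdsc = 0.9, status = "ok",
                                stringsAsFactors = FALSE))
  expect_error(compare_cohorts(rec5, st, "sdsc"), "cover")
})
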