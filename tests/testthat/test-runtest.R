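# Inferential core: autocorrelation estimation, pointwise t-tests,
# longest-run statistic, Monte Carlo null and interval extraction.

test_that("lag-1 autocorrelation has its closed-form limits", {
  expect_lt(abs(lag1_autocorrelation(rep(c(1, -1), 50)) - (-1)), 0.03)
  expect_gt(lag1_autocorrelation(seq_len(1000)), 0.99)
  x <- ar1_series(100000, 0.9, seed = 12)
  expect_lt(abs(lag1_autocorrelation(x) - 0.9), 0.02)
  expect_error(lag1_autocorrelation(rep(2, 50)),
               class = "vicarsep_degenerate")
  expect_error(lag1_autocorrelation(c(1, 2)),
               class = "vicarsep_invalid_parameter")
})

test_that("rho estimation averages rows, skips constants, reports rounded", {
  row <- ar1_series(101, 0.99, seed = 21)
  m <- rbind(row, row, row)
  est <- estimate_rho(m)
  expect_equal(attr(est, "raw"), lag1_autocorrelation(row))
  expect_equal(as.numeric(est), round(lag1_autocorrelation(row), 2))

  wn <- ar1_matrix(15, 1000, 0, seed = 22)
  expect_lt(abs(attr(estimate_rho(wn), "raw")), 0.05)

  m2 <- rbind(row, rep(1, 101))
  expect_warning(est2 <- estimate_rho(m2), "constant")
  expect_equal(attr(est2, "n_rows_used"), 1L)
  expect_error(suppressWarnings(estimate_rho(matrix(1, 3, 10))),
               class = "vicarsep_degenerate")
})

test_that("pointwise t-tests flag nothing on null data and calibrate at alpha", {
  z <- matrix(0, 5, 20)
  pt <- pointwise_t(z)
  expect_false(any(pt$significant))
  expect_equal(pt$df, 4)

  props <- with_seed(30, vapply(1:200, function(i) {
    mean(pointwise_t(matrix(stats::rnorm(15 * 50), 15, 50))$significant)
  }, numeric(1)))
  expect_gt(mean(props), 0.03)
  expect_lt(mean(props), 0.07)

  expect_error(pointwise_t(matrix(1, 1, 5)),
               class = "vicarsep_insufficient_data")
})

test_that("zero-variance columns are significant iff their mean is non-zero", {
  m <- matrix(stats::rnorm(50), 5, 10)
  m[, 3] <- 0       # zero variance, zero mean
  m[, 7] <- 2.2     # zero variance, non-zero mean
  pt <- pointwise_t(m)
  expect_false(pt$significant[3])
  expect_true(pt$significant[7])
  expect_setequal(pt$degenerate_columns, c(3, 7))
})

test_that("longest_run matches the brute-force oracle on every vector up to length 12", {
  expect_equal(longest_run(logical(0)), 0L)
  expect_equal(longest_run(rep(FALSE, 10)), 0L)
  expect_equal(longest_run(rep(TRUE, 7)), 7L)
  expect_equal(longest_run(c(FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE,
                             FALSE)), 3L)
  for (n in 1:12) {
    for (code in 0:(2^n - 1)) {
      v <- as.logical(bitwAnd(bitwShiftR(code, 0:(n - 1)), 1L))
      expect_identical(longest_run(v), longest_run_oracle(v))
    }
  }
  expect_error(longest_run(c(TRUE, NA)), class = "vicarsep_invalid_input")
})

test_that("the Monte Carlo null is reproducible and extends without reshuffling", {
  n1 <- simulate_null(15, 101, 0.9, n_sims = 100, seed = 40)
  n2 <- simulate_null(15, 101, 0.9, n_sims = 100, seed = 40)
  expect_identical(n1$run_lengths, n2$run_lengths)
  n3 <- simulate_null(15, 101, 0.9, n_sims = 150, seed = 40)
  expect_identical(n3$run_lengths[1:100], n1$run_lengths)
  expect_true(all(n1$run_lengths >= 0 & n1$run_lengths <= 101))
  expect_equal(n1$threshold_ms, n1$threshold_samples * 2)
})

test_that("the run-length threshold increases with autocorrelation and vanishes as alpha -> 0", {
  ths <- vapply(c(0, 0.5, 0.9, 0.99), function(r)
    simulate_null(15, 101, r, n_sims = 500, seed = 41)$threshold_samples,
    integer(1))
  expect_true(all(diff(ths) >= 0))
  expect_gt(ths[4], ths[1])
  tiny <- simulate_null(15, 101, 0.9, n_sims = 200, alpha = 1e-8,
                        seed = 42)
  expect_equal(tiny$threshold_samples, 0L)
  expect_error(simulate_null(15, 101, 1.2),
               class = "vicarsep_invalid_parameter")
})

test_that("interval extraction is strict: runs must exceed the threshold", {
  null <- simulate_null(5, 40, 0.5, n_sims = 200, seed = 43)
  thr <- null$threshold_samples
  expect_gt(thr, 0)
  tm <- (0:39) * 2
  mk <- function(runlen) {
    m <- matrix(0, 5, 40)
    if (runlen > 0) m[, seq_len(runlen)] <- 3   # degenerate but significant
    vicarsep:::new_diffmat(m, tm, "Contralateral")
  }
  at <- significant_intervals(mk(thr), null)
  expect_false(at$significant)
  expect_equal(nrow(at$intervals), 0)
  over <- significant_intervals(mk(thr + 1), null)
  expect_true(over$significant)
  expect_equal(over$intervals$length_samples, thr + 1)
  expect_equal(over$intervals$start_ms, 0)
  expect_equal(over$intervals$direction, "positive")
  expect_equal(over$intervals$mean_uV, 3 * (thr + 1) / (thr + 1))
  zero <- significant_intervals(mk(0), null)
  expect_false(zero$significant)
  wrong <- vicarsep:::new_diffmat(matrix(0, 4, 40), tm, "x")
  expect_error(significant_intervals(wrong, null),
               class = "vicarsep_invalid_input")
})

test_that("the full longest-run test recovers an embedded sustained effect", {
  tm <- seq(0, 200, by = 2)
  box <- tm >= 92 & tm <= 184
  with_seed(50, {
    m <- ar1_matrix(15, 101, 0.9) * 1.4
    m[, box] <- m[, box] - 2.74
  })
  dm <- vicarsep:::new_diffmat(m, tm, "Contralateral")
  fit <- sep_runtest(dm, seed = 51)
  expect_true(fit$significant)
  iv <- fit$intervals[fit$intervals$direction == "negative", ]
  expect_gt(nrow(iv), 0)
  expect_lt(iv$start_ms[1], 184)
  expect_gt(iv$end_ms[nrow(iv)], 92)
  expect_lt(iv$mean_uV[1], 0)
  # determinism of the fitted object under identical seeds
  expect_identical(fit$intervals, sep_runtest(dm, seed = 51)$intervals)
})

test_that("rho override and the simulate method behave", {
  m <- ar1_matrix(10, 60, 0.5, seed = 60)
  fit <- sep_runtest(m, rho = 0.8, n_sims = 200, seed = 61,
                     sample_interval_ms = 2)
  expect_equal(fit$rho_used, 0.8)
  expect_equal(fit$null$rho, 0.8)
  draws <- simulate(fit, nsim = 50, seed = 62)
  expect_length(draws, 50)
  expect_identical(draws, simulate(fit, nsim = 50, seed = 62))
  # constant matrix: rho inestimable without an override
  cz <- matrix(1, 5, 30)
  expect_error(suppressWarnings(sep_runtest(cz, n_sims = 10)),
               class = "vicarsep_degenerate")
  fitz <- suppressWarnings(sep_runtest(cz, rho = 0.3, n_sims = 50,
                                       seed = 63))
  expect_true(fitz$significant)  # zero-variance non-zero mean everywhere
})
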