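# The inferential core: pointwise one-sample t-tests on a participants x
# samples difference matrix, the longest-run statistic, and the AR(1)
# Monte Carlo null that converts run length into a familywise-calibrated
# duration threshold.

#' Sample lag-1 autocorrelation
#'
#' Mean-centred first-order autocorrelation with the series variance as
#' denominator:
#' \eqn{r_1 = \sum_{t<n}(x_t-\bar x)(x_{t+1}-\bar x) / \sum_t (x_t-\bar x)^2}.
#'
#' @param x numeric vector, length at least 3, not constant.
#' @return lag-1 autocorrelation in `[-1, 1]`.
#' @export
lag1_autocorrelation <- function(x) {
  if (length(x) < 3L) {
    stop_vicarsep("need at least 3 samples", "vicarsep_invalid_parameter")
  }
  xc <- x - mean(x)
  denom <- sum(xc^2)
  if (denom == 0) {
    stop_vicarsep("lag-1 autocorrelation is undefined for a constant series",
                  "vicarsep_degenerate")
  }
  sum(xc[-1L] * xc[-length(xc)]) / denom
}

#' Average lag-1 autocorrelation of difference waveforms
#'
#' Computes [lag1_autocorrelation()] for every participant row of a
#' difference matrix and averages across participants. Constant rows are
#' skipped with a warning. The return value is rounded to `digits`
#' decimals for reporting; the raw average is kept in the `"raw"`
#' attribute and is what [sep_runtest()] feeds into the null simulation.
#'
#' @param matrix a `"diffmat"` or plain numeric matrix (rows =
#'   participants).
#' @param digits decimals for the reported value (default 2).
#' @return rounded average lag-1 autocorrelation with attribute `"raw"`.
#' @export
estimate_rho <- function(matrix, digits = 2) {
  m <- unclass(matrix)
  if (!is.matrix(m) || nrow(m) < 1L) {
    stop_vicarsep("matrix must have at least one row",
                  "vicarsep_invalid_input")
  }
  r1 <- rep(NA_real_, nrow(m))
  for (i in seq_len(nrow(m))) {
    r1[i] <- tryCatch(lag1_autocorrelation(m[i, ]),
                      vicarsep_degenerate = function(e) {
                        warning(sprintf("row %d constant; skipped in rho estimate", i),
                                call. = FALSE)
                        NA_real_
                      })
  }
  if (all(is.na(r1))) {
    stop_vicarsep("all rows constant; rho undefined", "vicarsep_degenerate")
  }
  raw <- mean(r1, na.rm = TRUE)
  structure(round(raw, digits), raw = raw, n_rows_used = sum(!is.na(r1)))
}

#' Pointwise one-sample t-tests against zero
#'
#' Two-tailed one-sample t-test (versus zero) at every time sample of a
#' participants x samples matrix, with `nrow - 1` degrees of freedom and no
#' multiple-comparison correction; significance of each sample is decided
#' at level `alpha`. Degenerate zero-variance columns are significant when
#' their common value is non-zero and not significant when it is zero, and
#' are flagged.
#'
#' @param matrix numeric matrix (at least two rows).
#' @param alpha two-tailed significance level (default 0.05).
#' @return list with `t` (statistics), `significant` (logical per sample),
#'   `df`, `critical` (two-tailed critical value) and
#'   `degenerate_columns`.
#' @export
pointwise_t <- function(matrix, alpha = 0.05) {
  m <- unclass(matrix)
  if (!is.matrix(m) || nrow(m) < 2L) {
    stop_vicarsep("pointwise t-tests need at least two participants",
                  "vicarsep_insufficient_data")
  }
  if (alpha <= 0 || alpha >= 1) {
    stop_vicarsep("alpha must be in (0, 1)", "vicarsep_invalid_parameter")
  }
  n <- nrow(m)
  mu <- colMeans(m)
  v <- (colSums(m^2) - n * mu^2) / (n - 1)
  v[v < 0] <- 0  # numerical guard
  se <- sqrt(v / n)
  tv <- ifelse(se > 0, mu / se, ifelse(mu == 0, 0, sign(mu) * Inf))
  crit <- stats::qt(1 - alpha / 2, df = n - 1)
  list(t = tv, significant = abs(tv) > crit, df = n - 1, critical = crit,
       degenerate_columns = which(se == 0))
}

#' Longest run of consecutive TRUE values
#'
#' The longest-run statistic: length (in samples) of the maximal block of
#' consecutive significant time points; 0 if there are none.
#'
#' @param significant logical vector (no missing values).
#' @return integer count.
#' @examples
#' longest_run(c(FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE))
#' @export
longest_run <- function(significant) {
  if (length(significant) == 0L) return(0L)
  if (anyNA(significant) || !is.logical(significant)) {
    stop_vicarsep("significant must be a logical vector without NA",
                  "vicarsep_invalid_input")
  }
  r <- rle(significant)
  lens <- r$lengths[r$values]
  if (length(lens)) max(lens) else 0L
}

# Longest run per column of a logical matrix (samples x sims).
longest_run_cols <- function(sig) {
  vapply(seq_len(ncol(sig)), function(j) longest_run(sig[, j]), integer(1))
}

#' Monte Carlo null distribution of the longest-run statistic
#'
#' Simulates `n_sims` null data sets, each consisting of `n_participants`
#' independent stationary AR(1) waveforms (zero mean, unit variance, lag-1
#' autocorrelation `rho`) of `n_samples` points; applies the pointwise
#' t-tests of [pointwise_t()] to each and records the longest run of
#' consecutive significant samples. The duration threshold is the
#' nearest-rank `percentile` of the `n_sims` run lengths, converted to ms
#' with the sample interval.
#'
#' Innovations are drawn in per-simulation contiguous blocks, so enlarging
#' `n_sims` under the same seed extends the distribution without changing
#' earlier simulations.
#'
#' @param n_participants simulated participants per data set (>= 2).
#' @param n_samples time samples per waveform (>= 2).
#' @param rho lag-1 autocorrelation in `[0, 1)`.
#' @param n_sims number of simulated data sets (default 1000).
#' @param alpha two-tailed pointwise significance level (default 0.05).
#' @param percentile percentile of the run-length distribution defining
#'   the threshold (default 95).
#' @param sample_interval_ms ms per sample (default 2, i.e. 500 Hz).
#' @param seed optional seed (caller's RNG state restored).
#' @return object of class `"null_run_dist"` with `run_lengths`,
#'   `threshold_samples`, `threshold_ms` and the simulation parameters.
#' @examples
#' nd <- simulate_null(15, 101, 0.9, n_sims = 200, seed = 1)
#' nd$threshold_ms
#' @export
simulate_null <- function(n_participants, n_samples, rho, n_sims = 1000,
                          alpha = 0.05, percentile = 95,
                          sample_interval_ms = 2, seed = NULL) {
  check_rho(rho)
  if (n_participants < 2 || n_samples < 2) {
    stop_vicarsep("need at least 2 participants and 2 samples",
                  "vicarsep_invalid_parameter")
  }
  if (n_sims < 1) {
    stop_vicarsep("n_sims must be at least 1", "vicarsep_invalid_parameter")
  }
  if (percentile <= 0 || percentile >= 100) {
    stop_vicarsep("percentile must be in (0, 100)",
                  "vicarsep_invalid_parameter")
  }
  n_participants <- as.integer(n_participants)
  n_samples <- as.integer(n_samples)
  n_sims <- as.integer(n_sims)
  crit <- stats::qt(1 - alpha / 2, df = n_participants - 1)
  s <- sqrt(1 - rho^2)
  chunk <- max(1L, as.integer(2e7 / (n_participants * n_samples)))
  runs <- integer(0)
  with_seed(seed, {
    done <- 0L
    while (done < n_sims) {
      k <- min(chunk, n_sims - done)
      # dim: participants x samples x sims, sim slowest-varying so each
      # simulation owns a contiguous innovation block
      A <- array(stats::rnorm(n_participants * n_samples * k),
                 dim = c(n_participants, n_samples, k))
      if (rho > 0) {
        A[, -1L, ] <- A[, -1L, ] * s
        for (t in 2:n_samples) {
          A[, t, ] <- A[, t, ] + rho * A[, t - 1L, ]
        }
      }
      mu <- colMeans(A)                  # samples x sims
      v <- (colMeans(A^2) - mu^2) * n_participants / (n_participants - 1)
      tv <- mu / sqrt(v / n_participants)
      runs <- c(runs, longest_run_cols(abs(tv) > crit))
      done <- done + k
    }
  })
  thr <- sort(runs)[ceiling(percentile / 100 * n_sims)]
  structure(list(run_lengths = runs,
                 threshold_samples = as.integer(thr),
                 threshold_ms = thr * sample_interval_ms,
                 rho = rho, n_participants = n_participants,
                 n_samples = n_samples, n_sims = n_sims, alpha = alpha,
                 percentile = percentile,
                 sample_interval_ms = sample_interval_ms, seed = seed),
            class = "null_run_dist")
}

#' @export
print.null_run_dist <- function(x, ...) {
  cat(sprintf("Monte Carlo longest-run null: %d sims, %d participants x %d samples, rho = %g\n",
              x$n_sims, x$n_participants, x$n_samples, x$rho))
  cat(sprintf("  %gth percentile threshold: %d samples (%g ms); run lengths %d-%d\n",
              x$percentile, x$threshold_samples, x$threshold_ms,
              min(x$run_lengths), max(x$run_lengths)))
  invisible(x)
}

#' Significant intervals from a difference matrix and a null distribution
#'
#' Applies the pointwise t-tests to the observed matrix and reports every
#' run of consecutive significant samples whose length *strictly* exceeds
#' the null threshold, as a time interval with the sign and mean amplitude
#' of the difference within it.
#'
#' @param matrix a `"diffmat"` (participants x samples, with a `time_ms`
#'   attribute).
#' @param null a [simulate_null()] result with matching dimensions.
#' @param alpha pointwise significance level (defaults to the null's).
#' @return object of class `"interval_report"`: data frame `intervals`
#'   (`start_ms`, `end_ms`, `direction`, `mean_uV`, `length_samples`,
#'   `length_ms`), `threshold_samples`, `threshold_ms`, `rho_used`,
#'   `significant`, plus the pointwise test results.
#' @export
significant_intervals <- function(matrix, null, alpha = null$alpha) {
  stopifnot(inherits(null, "null_run_dist"))
  m <- unclass(matrix)
  time_ms <- attr(matrix, "time_ms")
  if (is.null(time_ms)) {
    stop_vicarsep("matrix must carry a time_ms attribute",
                  "vicarsep_invalid_input")
  }
  if (nrow(m) != null$n_participants || ncol(m) != null$n_samples) {
    stop_vicarsep("matrix dimensions do not match the null distribution",
                  "vicarsep_invalid_input")
  }
  pt <- pointwise_t(m, alpha)
  r <- rle(pt$significant)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths > null$threshold_samples)
  ivs <- data.frame(start_ms = numeric(0), end_ms = numeric(0),
                    direction = character(0), mean_uV = numeric(0),
                    length_samples = integer(0), length_ms = numeric(0))
  for (j in keep) {
    cols <- starts[j]:ends[j]
    amp <- mean(m[, cols])
    ivs <- rbind(ivs, data.frame(
      start_ms = time_ms[starts[j]], end_ms = time_ms[ends[j]],
      direction = if (amp >= 0) "positive" else "negative",
      mean_uV = amp, length_samples = r$lengths[j],
      length_ms = r$lengths[j] * null$sample_interval_ms))
  }
  structure(list(intervals = ivs,
                 threshold_samples = null$threshold_samples,
                 threshold_ms = null$threshold_ms,
                 rho_used = null$rho,
                 significant = nrow(ivs) > 0L,
                 laterality = attr(matrix, "laterality"),
                 pointwise = pt, time_ms = time_ms),
            class = "interval_report")
}

#' @export
print.interval_report <- function(x, ...) {
  lat <- x$laterality %||% "difference"
  cat(sprintf("Longest-run test (%s): threshold %g ms (rho = %g)\n",
              lat, x$threshold_ms, x$rho_used))
  if (nrow(x$intervals) == 0L) {
    cat("  no run exceeded the threshold\n")
  } else {
    for (i in seq_len(nrow(x$intervals))) {
      iv <- x$intervals[i, ]
      cat(sprintf("  %g-%g ms, %s (mean %.2f uV, run %g ms)\n",
                  iv$start_ms, iv$end_ms, iv$direction, iv$mean_uV,
                  iv$length_ms))
    }
  }
  invisible(x)
}

#' Autocorrelation-calibrated longest-run test for difference waveforms
#'
#' The complete inferential procedure for one difference matrix: estimate
#' the average lag-1 autocorrelation of the participant difference
#' waveforms (unless `rho` is supplied), simulate the Monte Carlo null
#' distribution of the longest run of pointwise-significant samples at
#' that autocorrelation, and report every observed run strictly longer
#' than the nearest-rank percentile threshold. Controls the familywise
#' error of the waveform comparison without a pointwise multiplicity
#' correction.
#'
#' @param x a `"diffmat"` from [build_diff_matrix()] /
#'   [build_interaction_matrix()], or a plain participants x samples
#'   matrix (then `sample_interval_ms` supplies the time step and the time
#'   axis starts at 0).
#' @param rho optional lag-1 autocorrelation override; when `NULL` the raw
#'   average of the per-participant sample autocorrelations is used (the
#'   rounded value is reported alongside).
#' @param n_sims Monte Carlo simulations (default 1000).
#' @param alpha two-tailed pointwise significance level (default 0.05).
#' @param percentile run-length percentile defining the threshold
#'   (default 95).
#' @param sample_interval_ms ms per sample for plain-matrix input
#'   (default 2).
#' @param seed optional seed for the null simulation.
#' @return object of class `"sep_runtest"` with components `intervals`
#'   (data frame), `significant`, `null` (the [simulate_null()] object),
#'   `rho_used`, `rho_estimate` (rounded, with `"raw"` attribute, or `NA`
#'   if inestimable), `pointwise`, `matrix`, `call`. Methods: `print`,
#'   `summary`, `plot`, `simulate`.
#' @examples
#' m <- ar1_matrix(15, 101, 0.5, seed = 2)
#' fit <- sep_runtest(m, n_sims = 200, seed = 3)
#' fit
#' @export
sep_runtest <- function(x, rho = NULL, n_sims = 1000, alpha = 0.05,
                        percentile = 95, sample_interval_ms = 2,
                        seed = NULL) {
  if (!inherits(x, "diffmat")) {
    if (!is.matrix(x)) {
      stop_vicarsep("x must be a diffmat or a numeric matrix",
                    "vicarsep_invalid_input")
    }
    tm <- attr(x, "time_ms") %||%
      (seq_len(ncol(x)) - 1) * sample_interval_ms
    x <- new_diffmat(x, tm, attr(x, "laterality"))
  }
  tm <- attr(x, "time_ms")
  step <- if (length(tm) > 1) tm[2] - tm[1] else sample_interval_ms
  rho_est <- tryCatch(estimate_rho(x),
                      vicarsep_error = function(e) NA_real_)
  rho_used <- if (!is.null(rho)) rho else attr(rho_est, "raw")
  if (is.null(rho_used) || is.na(rho_used)) {
    stop_vicarsep("rho could not be estimated; supply it explicitly",
                  "vicarsep_degenerate")
  }
  rho_used <- max(0, min(rho_used, 1 - 1e-6))
  null <- simulate_null(nrow(x), ncol(x), rho_used, n_sims = n_sims,
                        alpha = alpha, percentile = percentile,
                        sample_interval_ms = step, seed = seed)
  res <- significant_intervals(x, null, alpha)
  structure(list(intervals = res$intervals,
                 significant = res$significant,
                 null = null, rho_used = rho_used,
                 rho_estimate = rho_est,
                 pointwise = res$pointwise,
                 matrix = x, alpha = alpha, seed = seed,
                 laterality = attr(x, "laterality"),
                 call = match.call()),
            class = "sep_runtest")
}

#' @export
print.sep_runtest <- function(x, ...) {
  cat("Autocorrelation-calibrated longest-run test\n")
  lat <- x$laterality %||% "difference"
  cat(sprintf("  data: %d participants x %d samples (%s)\n",
              nrow(x$matrix), ncol(x$matrix), lat))
  est <- if (is.na(x$rho_estimate[1])) "n/a" else
    sprintf("%.2f", as.numeric(x$rho_estimate))
  cat(sprintf("  rho used: %.4f (reported estimate %s); threshold: %g ms (%d samples, %gth pct of %d sims)\n",
              x$rho_used, est, x$null$threshold_ms,
              x$null$threshold_samples, x$null$percentile, x$null$n_sims))
  if (nrow(x$intervals) == 0L) {
    cat("  no significant interval\n")
  } else {
    for (i in seq_len(nrow(x$intervals))) {
      iv <- x$intervals[i, ]
      cat(sprintf("  significant %g-%g ms, %s, mean %.2f uV\n",
                  iv$start_ms, iv$end_ms, iv$direction, iv$mean_uV))
    }
  }
  invisible(x)
}

#' @export
summary.sep_runtest <- function(object, ...) {
  x <- object
  cat(sprintf("Pointwise t-tests: df = %d, two-tailed critical |t| = %.3f, alpha = %g\n",
              x$pointwise$df, x$pointwise$critical, x$alpha))
  cat(sprintf("  significant samples: %d of %d; longest observed run: %d samples\n",
              sum(x$pointwise$significant), ncol(x$matrix),
              longest_run(x$pointwise$significant)))
  qs <- stats::quantile(x$null$run_lengths, c(0.5, 0.9, 0.95, 0.99),
                        type = 1)
  cat("  null run-length quantiles (samples):\n")
  print(qs)
  print(x)
  invisible(x)
}

#' Plot a longest-run test
#'
#' Mean difference waveform with a pointwise 95 percent confidence band
#' and shading over the significant intervals.
#'
#' @param x a [sep_runtest()] object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.sep_runtest <- function(x, ...) {
  tm <- attr(x$matrix, "time_ms")
  m <- unclass(x$matrix)
  mu <- colMeans(m)
  se <- apply(m, 2, stats::sd) / sqrt(nrow(m))
  ci <- x$pointwise$critical * se
  graphics::plot(tm, mu, type = "n",
                 ylim = range(mu + ci, mu - ci, 0),
                 xlab = "time (ms)", ylab = "difference (uV)", ...)
  if (nrow(x$intervals) > 0L) {
    usr <- graphics::par("usr")
    for (i in seq_len(nrow(x$intervals))) {
      graphics::rect(x$intervals$start_ms[i], usr[3],
                     x$intervals$end_ms[i], usr[4],
                     col = "grey90", border = NA)
    }
  }
  graphics::polygon(c(tm, rev(tm)), c(mu + ci, rev(mu - ci)),
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    border = NA)
  graphics::lines(tm, mu, lwd = 2, col = "steelblue4")
  graphics::abline(h = 0, lty = 3)
  graphics::box()
  invisible(x)
}

#' Simulate longest-run statistics from a fitted test's null model
#'
#' Draws `nsim` further null longest-run values at the fitted
#' autocorrelation and dimensions.
#'
#' @param object a [sep_runtest()] object.
#' @param nsim number of null simulations (default 100).
#' @param seed optional seed.
#' @param ... unused.
#' @return integer vector of simulated longest-run lengths (samples).
#' @export
simulate.sep_runtest <- function(object, nsim = 100, seed = NULL, ...) {
  nd <- simulate_null(object$null$n_participants, object$null$n_samples,
                      object$null$rho, n_sims = nsim,
                      alpha = object$null$alpha,
                      percentile = object$null$percentile,
                      sample_interval_ms = object$null$sample_interval_ms,
                      seed = seed)
  nd$run_lengths
}
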