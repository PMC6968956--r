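#' Stationary AR(1) series with unit marginal variance
#'
#' Generates a first-order autoregressive Gaussian series
#' \eqn{x_t = \rho x_{t-1} + \sqrt{1-\rho^2}\,\epsilon_t} with
#' \eqn{x_1 \sim N(0,1)}, so that every time point has zero mean, unit
#' variance and lag-1 autocorrelation \eqn{\rho}. This is the null model
#' for simulated difference waveforms: smooth autocorrelated noise with
#' no condition effect.
#'
#' @param n_samples number of time samples (at least 2).
#' @param rho lag-1 autocorrelation, in `[0, 1)`.
#' @param seed optional integer seed; the caller's RNG state is restored.
#' @return numeric vector of length `n_samples`.
#' @examples
#' x <- ar1_series(500, 0.9, seed = 1)
#' cor(x[-1], x[-length(x)])
#' @export
ar1_series <- function(n_samples, rho, seed = NULL) {
  drop(ar1_matrix(1L, n_samples, rho, seed = seed))
}

#' Matrix of independent stationary AR(1) series
#'
#' Each row is an independent series as in [ar1_series()]. Used both by the
#' synthetic EEG generator (per-channel noise) and to build replicate null
#' difference matrices.
#'
#' @param n_series number of independent rows.
#' @param n_samples samples per row (at least 2).
#' @inheritParams ar1_series
#' @return `n_series` x `n_samples` numeric matrix.
#' @export
ar1_matrix <- function(n_series, n_samples, rho, seed = NULL) {
  check_rho(rho)
  if (!is.numeric(n_samples) || length(n_samples) != 1L || n_samples < 2) {
    stop_vicarsep("n_samples must be a single integer >= 2",
                  "vicarsep_invalid_parameter")
  }
  n_series <- as.integer(n_series)
  n_samples <- as.integer(n_samples)
  with_seed(seed, {
    x <- matrix(stats::rnorm(n_series * n_samples), n_series, n_samples)
    s <- sqrt(1 - rho^2)
    if (rho > 0) {
      x[, -1L] <- x[, -1L] * s
      for (t in 2:n_samples) x[, t] <- x[, t] + rho * x[, t - 1L]
    }
    x
  })
}
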