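# Zero-phase IIR low-pass filtering, vectorised over many short series.
#
# The filter is designed with signal::ellip(); the forward-backward pass
# reproduces signal::filtfilt()'s zero-padding scheme exactly but runs on a
# whole matrix of series at once through stats::filter(), which is what makes
# filtering hundreds of (trial, channel) epochs per participant cheap.

design_lowpass <- function(sampling_rate, cutoff_hz, order = 5,
                           ripple_db = 0.5, stopband_db = 40) {
  if (cutoff_hz <= 0 || cutoff_hz >= sampling_rate / 2) {
    stop_vicarsep("low-pass cutoff must lie strictly below the Nyquist frequency",
                  "vicarsep_invalid_parameter")
  }
  signal::ellip(order, ripple_db, stopband_db, cutoff_hz / (sampling_rate / 2))
}

# One causal IIR pass on every column of X, zero initial conditions
# (same convention as signal::filter.default).
iir_cols <- function(b, a, X) {
  n <- nrow(X)
  k <- ncol(X)
  bn <- b / a[1]
  # FIR part as shifted-matrix accumulation (zero initial history)
  Y <- bn[1] * X
  for (j in seq_along(bn)[-1]) {
    if (bn[j] != 0 && j <= n) {
      Y[j:n, ] <- Y[j:n, , drop = FALSE] +
        bn[j] * X[seq_len(n - j + 1L), , drop = FALSE]
    }
  }
  if (length(a) >= 2L) {
    Y <- matrix(stats::filter(Y, -a[-1] / a[1], method = "recursive"),
                n, k)
  }
  Y
}

# Forward-backward (zero-phase) filtering of every column of X.
filtfilt_cols <- function(filt, X) {
  b <- filt$b
  a <- filt$a
  npad <- 2L * max(length(a), length(b))
  n <- nrow(X)
  Xp <- rbind(X, matrix(0, npad, ncol(X)))
  Y <- iir_cols(b, a, Xp)
  Y <- iir_cols(b, a, Y[rev(seq_len(nrow(Y))), , drop = FALSE])
  Y <- Y[rev(seq_len(nrow(Y))), , drop = FALSE]
  Y[seq_len(n), , drop = FALSE]
}
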