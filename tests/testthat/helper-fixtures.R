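# Fixtures built in code: small epochsets and configs reused across tests.

six_channels <- function() unlist(analysis_electrodes(), use.names = FALSE)

# Minimal epochset: 6 analysis channels, arbitrary data.
make_epochset <- function(data = NULL, n_trials = 4, n_samples = 401,
                          sampling_rate = 500,
                          t_start = -100,
                          condition = rep(c("Hand", "Surface"),
                                          length.out = n_trials),
                          hand = rep(c("Left", "Right"),
                                     length.out = n_trials),
                          channels = six_channels(),
                          participant_id = "T01") {
  step <- 1000 / sampling_rate
  time_ms <- t_start + (seq_len(n_samples) - 1) * step
  if (is.null(data)) {
    data <- array(0, c(n_trials, length(channels), n_samples))
  }
  epochset(data, time_ms, condition, hand, channels, sampling_rate,
           participant_id = participant_id)
}

make_noise_epochset <- function(seed, n_trials = 4, n_samples = 401,
                                sd = 1, ...) {
  es <- make_epochset(n_trials = n_trials, n_samples = n_samples, ...)
  es$data <- with_seed(seed, array(stats::rnorm(length(es$data), sd = sd),
                                   dim(es$data)))
  es
}

with_seed <- vicarsep:::with_seed

# Small, fast generator config (physics intact, sizes reduced).
small_gen_config <- function(n_participants = 4, n_trials_per_condition = 6,
                             n_dummy_channels = 4, ...) {
  sep_gen_config(n_participants = n_participants,
                 n_trials_per_condition = n_trials_per_condition,
                 n_dummy_channels = n_dummy_channels, ...)
}

# Brute-force longest-run oracle: scan every contiguous block.
longest_run_oracle <- function(x) {
  best <- 0L
  n <- length(x)
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (all(x[i:j])) best <- max(best, j - i + 1L)
    }
  }
  best
}
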