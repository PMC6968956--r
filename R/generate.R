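#' Configuration for the synthetic SEP study generator
#'
#' Describes the simulated study: epoched multi-channel EEG for
#' `n_participants` infants, with AR(1) temporal noise on every channel, a
#' smooth positive SEP template peaking near `peak_latency_ms` on the six
#' analysis electrodes, and condition-by-laterality amplitude effects
#' confined to the configured time windows.
#'
#' The `hand_mean`/`surface_mean` entries of `effect_contra`/`effect_ipsi`
#' are *absolute targets*: the condition-mean amplitude (in microvolts,
#' averaged over the effect window) that the corresponding cluster SEP
#' should show *after* the standard preprocessing chain (30 Hz zero-phase
#' low-pass, baseline correction, average reference, cluster averaging).
#' Because average referencing mixes activity across clusters, the injected
#' raw amplitudes are calibrated against the actual noise-free
#' preprocessing operator (see [simulate_epochs()]); defaults are the
#' observed infant condition means. Setting `effect_contra` and
#' `effect_ipsi` to `NULL` disables injection entirely so every trial's
#' expected signal is the bare template.
#'
#' @param n_participants number of participants (default 15).
#' @param n_trials_per_condition trials generated per condition before
#'   artifact attrition (default 25; with the default attrition rate about
#'   18 survive rejection, matching typical artifact-free infant trial
#'   counts).
#' @param sampling_rate Hz (default 500).
#' @param epoch_window ms pair spanning stimulus onset (default
#'   `c(-100, 700)`).
#' @param rho lag-1 autocorrelation of the per-channel AR(1) noise,
#'   in `[0, 1)` (default 0.99).
#' @param noise_sd per-trial, per-channel noise standard deviation in
#'   microvolts (default 5; gives retained-trial cluster averages
#'   unit-order variability).
#' @param peak_latency_ms latency of the positive SEP template peak
#'   (default 130).
#' @param peak_fwhm_ms full width at half maximum of the Gaussian template
#'   (default 60).
#' @param peak_amplitude_uv raw template peak amplitude on the analysis
#'   electrodes before re-referencing (default 6).
#' @param effect_contra,effect_ipsi `NULL`, or lists with `hand_mean`,
#'   `surface_mean` (microvolts) and `window` (ms pair) describing the
#'   post-preprocessing condition means on the contralateral and
#'   ipsilateral clusters.
#' @param effect_sd_ratio between-participant SD of each laterality's
#'   condition difference, as a fraction of its absolute group mean
#'   (default 0.5).
#' @param attrition_rate probability that a trial carries a large
#'   artifact excursion (default 0.28).
#' @param artifact_amplitude_uv peak amplitude of the injected artifact
#'   excursion (default 400, comfortably beyond the 200 microvolt
#'   peak-to-peak rejection criterion).
#' @param n_dummy_channels extra non-analysis channels carrying only noise,
#'   included so average referencing has a realistic denominator
#'   (default 10).
#' @param seed master seed for the whole study; `NULL` leaves the RNG
#'   stream untouched.
#' @return object of class `"sep_gen_config"`.
#' @export
sep_gen_config <- function(n_participants = 15,
                           n_trials_per_condition = 25,
                           sampling_rate = 500,
                           epoch_window = c(-100, 700),
                           rho = 0.99,
                           noise_sd = 5,
                           peak_latency_ms = 130,
                           peak_fwhm_ms = 60,
                           peak_amplitude_uv = 6,
                           effect_contra = list(hand_mean = 3.06,
                                                surface_mean = 5.80,
                                                window = c(92, 184)),
                           effect_ipsi = list(hand_mean = 0.94,
                                              surface_mean = -1.07,
                                              window = c(66, 166)),
                           effect_sd_ratio = 0.5,
                           attrition_rate = 0.28,
                           artifact_amplitude_uv = 400,
                           n_dummy_channels = 10,
                           seed = NULL) {
  check_window(epoch_window, "epoch_window")
  if (!(epoch_window[1] < 0 && epoch_window[2] > 0)) {
    stop_vicarsep("epoch_window must span stimulus onset (start < 0 < end)",
                  "vicarsep_invalid_parameter")
  }
  check_rho(rho)
  if (n_participants < 2) {
    stop_vicarsep("n_participants must be at least 2",
                  "vicarsep_invalid_parameter")
  }
  if (attrition_rate < 0 || attrition_rate >= 1) {
    stop_vicarsep("attrition_rate must be in [0, 1)",
                  "vicarsep_invalid_parameter")
  }
  if (noise_sd < 0) {
    stop_vicarsep("noise_sd must be non-negative",
                  "vicarsep_invalid_parameter")
  }
  if (is.null(effect_contra) != is.null(effect_ipsi)) {
    stop_vicarsep("effect_contra and effect_ipsi must both be set or both be NULL",
                  "vicarsep_invalid_parameter")
  }
  for (eff in list(effect_contra, effect_ipsi)) {
    if (is.null(eff)) next
    if (!all(c("hand_mean", "surface_mean", "window") %in% names(eff))) {
      stop_vicarsep("effects need hand_mean, surface_mean and window",
                    "vicarsep_invalid_parameter")
    }
    check_window(eff$window, "effect window")
    if (eff$window[1] < 0 || eff$window[2] > epoch_window[2]) {
      stop_vicarsep("effect windows must lie inside [0, epoch end]",
                    "vicarsep_invalid_parameter")
    }
  }
  structure(
    list(n_participants = as.integer(n_participants),
         n_trials_per_condition = as.integer(n_trials_per_condition),
         sampling_rate = sampling_rate,
         epoch_window = epoch_window,
         rho = rho, noise_sd = noise_sd,
         peak_latency_ms = peak_latency_ms,
         peak_fwhm_ms = peak_fwhm_ms,
         peak_amplitude_uv = peak_amplitude_uv,
         effect_contra = effect_contra, effect_ipsi = effect_ipsi,
         effect_sd_ratio = effect_sd_ratio,
         attrition_rate = attrition_rate,
         artifact_amplitude_uv = artifact_amplitude_uv,
         n_dummy_channels = as.integer(n_dummy_channels),
         seed = seed),
    class = "sep_gen_config")
}

gen_time_axis <- function(config) {
  step <- 1000 / config$sampling_rate
  seq(config$epoch_window[1], config$epoch_window[2], by = step)
}

gen_channels <- function(config) {
  el <- unlist(analysis_electrodes(), use.names = FALSE)
  dummies <- setdiff(seq_len(200L), el)[seq_len(config$n_dummy_channels)]
  c(analysis_electrodes()$left, analysis_electrodes()$right, dummies)
}

# Gaussian SEP template (unit peak) on the time axis.
gen_template <- function(config, time_ms = gen_time_axis(config)) {
  exp(-4 * log(2) * ((time_ms - config$peak_latency_ms) /
                       config$peak_fwhm_ms)^2)
}

# Noise-free single-trial epochset carrying an arbitrary channels x samples
# mean structure for each hand; used to probe the preprocessing operator.
probe_epochset <- function(config, signal_left, signal_right) {
  time_ms <- gen_time_axis(config)
  channels <- gen_channels(config)
  data <- array(0, c(2L, length(channels), length(time_ms)))
  data[1L, , ] <- signal_left
  data[2L, , ] <- signal_right
  epochset(data, time_ms, condition = c("Hand", "Hand"),
           hand = c("Left", "Right"), channels = channels,
           sampling_rate = config$sampling_rate,
           participant_id = "probe")
}

# Post-preprocessing window mean of the contra/ipsi cluster SEP for a
# channels x samples mean structure (mirrored across hands).
probe_response <- function(config, build_signal) {
  channels <- gen_channels(config)
  sig <- lapply(c("Left", "Right"), function(h) build_signal(h, channels))
  es <- probe_epochset(config, sig[[1]], sig[[2]])
  pc <- preproc_config()
  es <- rereference_average(baseline_correct(lowpass_filter(es, pc), pc))
  contra <- average_sep(es, "Hand", "Contralateral", pc)
  ipsi <- average_sep(es, "Hand", "Ipsilateral", pc)
  c(window_mean_amplitude(contra, config$effect_contra$window),
    window_mean_amplitude(ipsi, config$effect_ipsi$window))
}

# Calibrate raw injection amplitudes so that post-preprocessing condition
# window means hit the configured targets. Returns the 2x2 response matrix
# of the unit contra/ipsi box-car injections and the template contribution.
injection_gains <- function(config) {
  if (is.null(config$effect_contra)) return(NULL)
  time_ms <- gen_time_axis(config)
  g <- gen_template(config, time_ms)
  el <- analysis_electrodes()
  box_c <- as.numeric(time_ms >= config$effect_contra$window[1] &
                        time_ms <= config$effect_contra$window[2])
  box_i <- as.numeric(time_ms >= config$effect_ipsi$window[1] &
                        time_ms <= config$effect_ipsi$window[2])
  on_cluster <- function(channels, ids, wave) {
    m <- matrix(0, length(channels), length(wave))
    m[match(ids, channels), ] <- rep(wave, each = length(ids))
    m
  }
  contra_ids <- function(h) if (h == "Left") el$right else el$left
  ipsi_ids <- function(h) if (h == "Left") el$left else el$right
  resp_template <- probe_response(config, function(h, ch)
    on_cluster(ch, unlist(el), g) * config$peak_amplitude_uv)
  resp_cbox <- probe_response(config, function(h, ch)
    on_cluster(ch, contra_ids(h), box_c))
  resp_ibox <- probe_response(config, function(h, ch)
    on_cluster(ch, ipsi_ids(h), box_i))
  list(M = cbind(resp_cbox, resp_ibox), template_contrib = resp_template)
}

#' Simulate one participant's epoched EEG
#'
#' Builds `2 * n_trials_per_condition` trials: independent AR(1) noise on
#' every channel, the SEP template on the six analysis electrodes, and
#' condition-dependent box-car amplitude offsets on the cluster
#' contralateral and ipsilateral to each trial's stimulated hand. Injection
#' amplitudes are calibrated (via `gains`, computed once per study) so the
#' noise-free preprocessed condition means equal the configured targets;
#' per-participant heterogeneity perturbs each laterality's condition
#' difference around its group mean. A fraction `attrition_rate` of trials
#' receives a large slow artifact excursion on one channel so that
#' amplitude-based rejection has realistic attrition.
#'
#' Deterministic given `config$seed` and `participant_id`.
#'
#' @param config a [sep_gen_config()].
#' @param participant_id identifier (also seeds the participant's stream).
#' @param seed optional explicit seed overriding the derived one.
#' @param gains internal calibration object from a previous call; computed
#'   when `NULL`.
#' @return an [epochset()].
#' @export
simulate_epochs <- function(config, participant_id = "P01", seed = NULL,
                            gains = NULL) {
  stopifnot(inherits(config, "sep_gen_config"))
  if (is.null(gains)) gains <- injection_gains(config)
  time_ms <- gen_time_axis(config)
  channels <- gen_channels(config)
  S <- length(time_ms)
  C <- length(channels)
  n_per <- config$n_trials_per_condition
  Tn <- 2L * n_per
  el <- analysis_electrodes()
  g <- gen_template(config, time_ms) * config$peak_amplitude_uv

  if (is.null(seed)) seed <- derive_seed(config$seed, id_hash(participant_id))

  with_seed(seed, {
    condition <- rep(c("Hand", "Surface"), each = n_per)
    hand <- c(sample(rep(c("Left", "Right"), length.out = n_per)),
              sample(rep(c("Left", "Right"), length.out = n_per)))

    # Per-participant condition targets (group targets +/- half the
    # heterogeneity draw, keeping the condition average fixed).
    offsets <- NULL
    if (!is.null(config$effect_contra)) {
      d_c <- config$effect_contra$surface_mean - config$effect_contra$hand_mean
      d_i <- config$effect_ipsi$surface_mean - config$effect_ipsi$hand_mean
      eta_c <- stats::rnorm(1, 0, config$effect_sd_ratio * abs(d_c))
      eta_i <- stats::rnorm(1, 0, config$effect_sd_ratio * abs(d_i))
      targets <- list(
        Hand = c(config$effect_contra$hand_mean - eta_c / 2,
                 config$effect_ipsi$hand_mean - eta_i / 2),
        Surface = c(config$effect_contra$surface_mean + eta_c / 2,
                    config$effect_ipsi$surface_mean + eta_i / 2))
      offsets <- lapply(targets, function(tg)
        solve(gains$M, tg - gains$template_contrib))
    }

    box_c <- if (is.null(config$effect_contra)) numeric(S) else
      as.numeric(time_ms >= config$effect_contra$window[1] &
                   time_ms <= config$effect_contra$window[2])
    box_i <- if (is.null(config$effect_ipsi)) numeric(S) else
      as.numeric(time_ms >= config$effect_ipsi$window[1] &
                   time_ms <= config$effect_ipsi$window[2])

    # Mean structure per (hand, condition): channels x samples.
    mean_structure <- function(h, k) {
      m <- matrix(0, C, S)
      m[match(unlist(el), channels), ] <- rep(g, each = 6L)
      if (!is.null(offsets)) {
        contra <- if (h == "Left") el$right else el$left
        ipsi <- if (h == "Left") el$left else el$right
        off <- offsets[[k]]
        m[match(contra, channels), ] <- m[match(contra, channels), ] +
          rep(off[1] * box_c, each = 3L)
        m[match(ipsi, channels), ] <- m[match(ipsi, channels), ] +
          rep(off[2] * box_i, each = 3L)
      }
      m
    }
    sigs <- list(Left = list(), Right = list())
    for (h in c("Left", "Right")) for (k in c("Hand", "Surface")) {
      sigs[[h]][[k]] <- mean_structure(h, k)
    }

    noise <- ar1_matrix(Tn * C, S, config$rho) * config$noise_sd
    data <- array(0, c(Tn, C, S))
    for (t in seq_len(Tn)) {
      data[t, , ] <- sigs[[hand[t]]][[condition[t]]] +
        noise[(t - 1L) * C + seq_len(C), ]
    }

    contaminated <- stats::runif(Tn) < config$attrition_rate
    if (any(contaminated)) {
      bump <- sin(pi * seq(0, 1, length.out = S)) *
        config$artifact_amplitude_uv
      for (t in which(contaminated)) {
        ch <- sample.int(C, 1L)
        data[t, ch, ] <- data[t, ch, ] + sample(c(-1, 1), 1L) * bump
      }
    }

    es <- epochset(data, time_ms, condition, hand, channels,
                   config$sampling_rate, participant_id = participant_id)
    attr(es, "contaminated") <- contaminated  # ground truth for tests
    es
  })
}

#' Simulate a full multi-participant study
#'
#' @param config a [sep_gen_config()].
#' @return list of [epochset()]s of length `config$n_participants`, class
#'   `"epochset_list"`.
#' @examples
#' study <- simulate_study(sep_gen_config(n_participants = 2, seed = 1))
#' length(study)
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sep_gen_config"))
  gains <- injection_gains(config)
  ids <- sprintf("P%02d", seq_len(config$n_participants))
  study <- lapply(ids, function(pid)
    simulate_epochs(config, pid, gains = gains))
  names(study) <- ids
  structure(study, class = "epochset_list")
}

#' @export
print.epochset_list <- function(x, ...) {
  cat(sprintf("Simulated SEP study: %d participants\n", length(x)))
  for (es in x) print(es)
  invisible(x)
}
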