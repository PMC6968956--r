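#' Preprocessing configuration
#'
#' Parameters of the standard SEP preprocessing chain, applied in the order
#' filter -> artifact rejection -> baseline correction -> average
#' reference -> averaging.
#'
#' @param lowpass_hz low-pass cutoff in Hz (default 30).
#' @param filter_order elliptic filter order (default 5; an odd order has
#'   exactly unit DC gain, so constant offsets pass the filter untouched).
#' @param passband_ripple_db,stopband_db elliptic design parameters
#'   (defaults 0.5 dB ripple, 40 dB stopband attenuation; the
#'   forward-backward pass doubles both in effect).
#' @param baseline_window ms pair over which the pre-stimulus mean is
#'   computed and subtracted (default `c(-100, 0)`); must end at or before
#'   stimulus onset.
#' @param rejection_threshold peak-to-peak amplitude criterion in
#'   microvolts; a trial whose range on any channel exceeds it is flagged
#'   as an artifact (default 200).
#' @param analysis_window ms pair to which difference waveforms are
#'   restricted for inference (default `c(0, 200)`, closed interval; at
#'   500 Hz this is 101 samples every 2 ms).
#' @return object of class `"preproc_config"`.
#' @export
preproc_config <- function(lowpass_hz = 30, filter_order = 5,
                           passband_ripple_db = 0.5, stopband_db = 40,
                           baseline_window = c(-100, 0),
                           rejection_threshold = 200,
                           analysis_window = c(0, 200)) {
  check_window(baseline_window, "baseline_window")
  check_window(analysis_window, "analysis_window")
  if (baseline_window[2] > 0) {
    stop_vicarsep("baseline_window must end at or before stimulus onset",
                  "vicarsep_invalid_parameter")
  }
  if (rejection_threshold <= 0) {
    stop_vicarsep("rejection_threshold must be positive",
                  "vicarsep_invalid_parameter")
  }
  structure(list(lowpass_hz = lowpass_hz, filter_order = filter_order,
                 passband_ripple_db = passband_ripple_db,
                 stopband_db = stopband_db,
                 baseline_window = baseline_window,
                 rejection_threshold = rejection_threshold,
                 analysis_window = analysis_window),
            class = "preproc_config")
}

#' Zero-phase low-pass filter all trials and channels
#'
#' Elliptic IIR low-pass applied forward and backward (zero phase, so
#' component latencies are not shifted). DC is preserved exactly with the
#' default odd filter order.
#'
#' @param epochs an [epochset()].
#' @param config a [preproc_config()].
#' @return the filtered [epochset()].
#' @export
lowpass_filter <- function(epochs, config = preproc_config()) {
  stopifnot(inherits(epochs, "epochset"))
  if (epochs$sampling_rate <= 2 * config$lowpass_hz) {
    stop_vicarsep("sampling rate must exceed twice the low-pass cutoff",
                  "vicarsep_invalid_parameter")
  }
  filt <- design_lowpass(epochs$sampling_rate, config$lowpass_hz,
                         config$filter_order, config$passband_ripple_db,
                         config$stopband_db)
  d <- dim(epochs$data)
  X <- matrix(aperm(epochs$data, c(3, 1, 2)), nrow = d[3])
  Xf <- filtfilt_cols(filt, X)
  epochs$data <- aperm(array(Xf, c(d[3], d[1], d[2])), c(2, 3, 1))
  epochs
}

#' Flag artifact trials by a peak-to-peak amplitude criterion
#'
#' A trial is flagged when its peak-to-peak amplitude on any channel
#' strictly exceeds `config$rejection_threshold`. Flagged trials are
#' excluded by all downstream averaging. If every trial of a condition is
#' rejected the participant is marked unusable (attribute `"unusable"`),
#' mirroring participant exclusion in infant studies.
#'
#' @inheritParams lowpass_filter
#' @return the [epochset()] with `is_artifact` set and a `"retained"`
#'   attribute holding per-condition retained-trial counts.
#' @export
reject_artifacts <- function(epochs, config = preproc_config()) {
  stopifnot(inherits(epochs, "epochset"))
  d <- dim(epochs$data)
  # peak-to-peak range per (trial, channel), then max over channels
  M <- matrix(aperm(epochs$data, c(3, 1, 2)), d[3])   # samples x (T*C)
  rng <- apply(M, 2, max) - apply(M, 2, min)
  pp <- apply(matrix(rng, d[1], d[2]), 1, max)
  epochs$is_artifact <- pp > config$rejection_threshold
  retained <- vapply(c(Hand = "Hand", Surface = "Surface"), function(k)
    sum(!epochs$is_artifact & epochs$condition == k), numeric(1))
  attr(epochs, "retained") <- retained
  if (any(retained == 0)) {
    attr(epochs, "unusable") <- TRUE
    warning(sprintf("participant %s: all trials rejected in at least one condition; flagged unusable",
                    epochs$participant_id), call. = FALSE)
  }
  epochs
}

#' Baseline-correct every trial and channel
#'
#' Subtracts, per trial and channel, the mean amplitude over the
#' pre-stimulus baseline window, so post-stimulus deflections are measured
#' relative to zero. Idempotent.
#'
#' @inheritParams lowpass_filter
#' @return the baseline-corrected [epochset()].
#' @export
baseline_correct <- function(epochs, config = preproc_config()) {
  stopifnot(inherits(epochs, "epochset"))
  bw <- config$baseline_window
  if (bw[1] < epochs$time_ms[1] - 1e-9 ||
      bw[2] > epochs$time_ms[length(epochs$time_ms)] + 1e-9) {
    stop_vicarsep("baseline window lies outside the epoch",
                  "vicarsep_invalid_parameter")
  }
  idx <- window_index(epochs$time_ms, bw, "baseline window")
  d <- dim(epochs$data)
  bl <- rowMeans(epochs$data[, , idx, drop = FALSE], dims = 2)
  epochs$data <- epochs$data - array(bl, d)
  epochs
}

#' Re-reference to the average potential over the scalp
#'
#' Subtracts, at each sample of each trial, the mean across all channels,
#' and tags the data as average-referenced. Idempotent; requires at least
#' two channels. A bare `trials x channels x samples` array may be passed
#' instead of an [epochset()], in which case the re-referenced array is
#' returned.
#'
#' @param epochs an [epochset()] or a 3-d numeric array.
#' @return the re-referenced [epochset()] (or array).
#' @export
rereference_average <- function(epochs) {
  if (is.array(epochs) && !inherits(epochs, "epochset")) {
    d <- dim(epochs)
    if (length(d) != 3L) {
      stop_vicarsep("array input must be trials x channels x samples",
                    "vicarsep_invalid_input")
    }
    if (d[2] < 2L) {
      stop_vicarsep("average referencing needs at least two channels",
                    "vicarsep_invalid_state")
    }
    chm <- colMeans(aperm(epochs, c(2, 1, 3)))
    return(epochs - aperm(array(chm, c(d[1], d[3], d[2])), c(1, 3, 2)))
  }
  stopifnot(inherits(epochs, "epochset"))
  d <- dim(epochs$data)
  if (d[2] < 2L) {
    stop_vicarsep("average referencing needs at least two channels",
                  "vicarsep_invalid_state")
  }
  chm <- colMeans(aperm(epochs$data, c(2, 1, 3)))  # trials x samples
  epochs$data <- epochs$data -
    aperm(array(chm, c(d[1], d[3], d[2])), c(1, 3, 2))
  epochs$reference <- "average"
  epochs
}

#' Run the full preprocessing chain
#'
#' Filter, reject artifacts, baseline-correct and average-reference, in
#' that order.
#'
#' @inheritParams lowpass_filter
#' @return the preprocessed [epochset()].
#' @export
preprocess_epochs <- function(epochs, config = preproc_config()) {
  epochs <- lowpass_filter(epochs, config)
  epochs <- reject_artifacts(epochs, config)
  epochs <- baseline_correct(epochs, config)
  rereference_average(epochs)
}

cluster_for_trial <- function(hand, laterality) {
  el <- analysis_electrodes()
  if (laterality == "Contralateral") {
    if (hand == "Left") el$right else el$left
  } else {
    if (hand == "Left") el$left else el$right
  }
}

#' Per-participant averaged SEP waveform
#'
#' For each retained trial of the requested condition, averages the
#' three-electrode cluster contralateral (or ipsilateral) to that trial's
#' stimulated hand, then averages across trials.
#'
#' @param epochs a preprocessed [epochset()].
#' @param condition `"Hand"` or `"Surface"`.
#' @param laterality `"Contralateral"` or `"Ipsilateral"`.
#' @param config a [preproc_config()] (unused fields tolerated; kept for a
#'   uniform stage signature).
#' @return object of class `"sep_waveform"`: `values` (microvolts per
#'   sample), `time_ms`, `n_trials_included`, labels.
#' @export
average_sep <- function(epochs, condition = c("Hand", "Surface"),
                        laterality = c("Contralateral", "Ipsilateral"),
                        config = preproc_config()) {
  stopifnot(inherits(epochs, "epochset"))
  condition <- match.arg(condition)
  laterality <- match.arg(laterality)
  keep <- which(!epochs$is_artifact & epochs$condition == condition)
  if (length(keep) == 0L) {
    stop_vicarsep(sprintf("participant %s has no retained %s trials",
                          epochs$participant_id, condition),
                  "vicarsep_missing_data")
  }
  S <- dim(epochs$data)[3]
  acc <- numeric(S)
  for (t in keep) {
    ids <- cluster_for_trial(epochs$hand[t], laterality)
    chidx <- match(ids, epochs$channels)
    m <- epochs$data[t, chidx, , drop = FALSE]
    dim(m) <- c(length(chidx), S)
    acc <- acc + colMeans(m)
  }
  structure(list(values = acc / length(keep), time_ms = epochs$time_ms,
                 participant_id = epochs$participant_id,
                 condition = condition, laterality = laterality,
                 n_trials_included = length(keep)),
            class = "sep_waveform")
}

#' @export
print.sep_waveform <- function(x, ...) {
  cat(sprintf("SEP waveform: %s, %s, %s (%d trials, %d samples)\n",
              x$participant_id, x$condition, x$laterality,
              x$n_trials_included, length(x$values)))
  invisible(x)
}

#' Build the participants x samples difference matrix
#'
#' Stacks per-participant Hand-minus-Surface difference waveforms at one
#' laterality, restricted to the analysis window (closed interval). This
#' matrix is the unit of inference for [sep_runtest()].
#'
#' @param seps list of [average_sep()] outputs covering both conditions for
#'   each participant at the requested laterality. Participants missing a
#'   condition are dropped with a warning.
#' @param laterality `"Contralateral"` or `"Ipsilateral"`.
#' @param config a [preproc_config()] (supplies the analysis window).
#' @return a `"diffmat"`: numeric matrix with participant row names and
#'   attributes `time_ms` and `laterality`.
#' @export
build_diff_matrix <- function(seps, laterality = c("Contralateral",
                                                   "Ipsilateral"),
                              config = preproc_config()) {
  laterality <- match.arg(laterality)
  seps <- Filter(function(w) w$laterality == laterality, seps)
  if (length(seps) == 0L) {
    stop_vicarsep("no waveforms at the requested laterality",
                  "vicarsep_invalid_input")
  }
  ids <- unique(vapply(seps, function(w) w$participant_id, character(1)))
  time_ms <- seps[[1]]$time_ms
  idx <- window_index(time_ms, config$analysis_window, "analysis window")
  rows <- list()
  for (pid in ids) {
    ws <- Filter(function(w) w$participant_id == pid, seps)
    hand <- Filter(function(w) w$condition == "Hand", ws)
    surf <- Filter(function(w) w$condition == "Surface", ws)
    if (length(hand) != 1L || length(surf) != 1L) {
      warning(sprintf("participant %s lacks a condition at %s; dropped",
                      pid, laterality), call. = FALSE)
      next
    }
    rows[[pid]] <- (hand[[1]]$values - surf[[1]]$values)[idx]
  }
  if (length(rows) == 0L) {
    stop_vicarsep("no participant contributed both conditions",
                  "vicarsep_missing_data")
  }
  m <- do.call(rbind, rows)
  new_diffmat(m, time_ms[idx], laterality)
}

new_diffmat <- function(m, time_ms, laterality) {
  structure(m, time_ms = as.numeric(time_ms), laterality = laterality,
            class = c("diffmat", class(matrix())))
}

#' Condition-by-hemisphere interaction matrix
#'
#' Row-wise double difference: contralateral minus ipsilateral difference
#' waveform per participant. A non-zero mean indicates that the condition
#' effect differs across hemispheres.
#'
#' @param contra,ipsi `"diffmat"` objects over the same participants and
#'   time axis.
#' @return a `"diffmat"` tagged `"interaction"`.
#' @export
build_interaction_matrix <- function(contra, ipsi) {
  stopifnot(inherits(contra, "diffmat"), inherits(ipsi, "diffmat"))
  if (!identical(rownames(contra), rownames(ipsi)) ||
      !isTRUE(all.equal(attr(contra, "time_ms"), attr(ipsi, "time_ms")))) {
    stop_vicarsep("contra and ipsi matrices must share participants and time axis",
                  "vicarsep_invalid_input")
  }
  new_diffmat(unclass(contra) - unclass(ipsi), attr(contra, "time_ms"),
              "interaction")
}

#' Mean amplitude over a time window
#'
#' Grand mean over participants (rows, if any) and all samples inside the
#' closed window.
#'
#' @param x a `"diffmat"` or `"sep_waveform"`.
#' @param window ms pair.
#' @return mean amplitude in microvolts.
#' @export
window_mean_amplitude <- function(x, window) {
  if (inherits(x, "sep_waveform")) {
    idx <- window_index(x$time_ms, window)
    return(mean(x$values[idx]))
  }
  if (inherits(x, "diffmat") || (is.matrix(x) && !is.null(attr(x, "time_ms")))) {
    idx <- window_index(attr(x, "time_ms"), window)
    return(mean(unclass(x)[, idx]))
  }
  stop_vicarsep("x must be a sep_waveform or a diffmat",
                "vicarsep_invalid_input")
}

#' Preprocess a study and assemble the three difference matrices
#'
#' Runs [preprocess_epochs()] for every participant, drops participants
#' flagged unusable (with a message), computes the four per-participant
#' SEPs (condition x laterality) and returns the contralateral,
#' ipsilateral and interaction difference matrices plus bookkeeping.
#'
#' @param study an `"epochset_list"` from [simulate_study()] (or any list
#'   of [epochset()]s).
#' @param config a [preproc_config()].
#' @return list with elements `contra`, `ipsi`, `interaction` (diffmats),
#'   `seps` (list of sep_waveforms), `retained` (data frame of retained
#'   trial counts) and `dropped` (character vector of excluded
#'   participants).
#' @export
sep_diff_matrices <- function(study, config = preproc_config()) {
  seps <- list()
  retained <- list()
  dropped <- character(0)
  for (es in study) {
    pp <- withCallingHandlers(
      preprocess_epochs(es, config),
      warning = function(w) {
        if (grepl("flagged unusable", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    if (isTRUE(attr(pp, "unusable"))) {
      message(sprintf("dropping participant %s: no retained trials in a condition",
                      pp$participant_id))
      dropped <- c(dropped, pp$participant_id)
      next
    }
    retained[[pp$participant_id]] <- attr(pp, "retained")
    for (k in c("Hand", "Surface")) for (lat in c("Contralateral",
                                                  "Ipsilateral")) {
      seps[[length(seps) + 1L]] <- average_sep(pp, k, lat, config)
    }
  }
  if (length(seps) == 0L) {
    stop_vicarsep("no usable participants", "vicarsep_missing_data")
  }
  contra <- build_diff_matrix(seps, "Contralateral", config)
  ipsi <- build_diff_matrix(seps, "Ipsilateral", config)
  list(contra = contra, ipsi = ipsi,
       interaction = build_interaction_matrix(contra, ipsi),
       seps = seps,
       retained = data.frame(
         participant = names(retained),
         hand = vapply(retained, `[[`, numeric(1), "Hand"),
         surface = vapply(retained, `[[`, numeric(1), "Surface"),
         row.names = NULL),
       dropped = dropped)
}
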