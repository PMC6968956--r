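#' Analysis electrode clusters
#'
#' The six centroparietal electrodes (geodesic net numbering) used for all
#' SEP analyses: 41, 46, 47 over the left hemisphere (around CP3) and 98,
#' 102, 103 over the right hemisphere (around CP4). The cluster
#' contralateral to a stimulated hand is the one on the opposite hemisphere.
#'
#' @return named list with integer vectors `left` and `right`.
#' @export
analysis_electrodes <- function() {
  list(left = c(41L, 46L, 47L), right = c(98L, 102L, 103L))
}

#' Construct an epoched EEG data set for one participant
#'
#' Container for one participant's epoched trials: a `trials x channels x
#' samples` array of microvolt values plus per-trial condition
#' (`"Hand"`/`"Surface"`) and stimulated-hand (`"Left"`/`"Right"`) labels.
#'
#' @param data numeric array, `trials x channels x samples` (microvolts).
#' @param time_ms numeric vector of sample times in ms relative to stimulus
#'   onset; must be strictly increasing with a constant step.
#' @param condition character vector, one of `"Hand"`/`"Surface"` per trial.
#' @param hand character vector, one of `"Left"`/`"Right"` per trial.
#' @param channels integer channel identifiers (must contain all six
#'   analysis electrodes, see [analysis_electrodes()]).
#' @param sampling_rate sampling rate in Hz.
#' @param reference reference tag, `"vertex"` or `"average"`.
#' @param is_artifact logical per-trial artifact flag (normally set by
#'   [reject_artifacts()]).
#' @param participant_id identifier.
#' @return object of class `"epochset"`.
#' @export
epochset <- function(data, time_ms, condition, hand, channels,
                     sampling_rate, reference = "vertex",
                     is_artifact = rep(FALSE, dim(data)[1]),
                     participant_id = "P01") {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop_vicarsep("data must be a trials x channels x samples array",
                  "vicarsep_invalid_input")
  }
  d <- dim(data)
  if (length(time_ms) != d[3]) {
    stop_vicarsep("time_ms length must equal the number of samples",
                  "vicarsep_invalid_input")
  }
  steps <- diff(time_ms)
  if (any(steps <= 0) || diff(range(steps)) > 1e-6) {
    stop_vicarsep("time_ms must be strictly increasing with a constant step",
                  "vicarsep_invalid_input")
  }
  if (abs(steps[1] - 1000 / sampling_rate) > 1e-6) {
    stop_vicarsep("time step must equal 1000 / sampling_rate ms",
                  "vicarsep_invalid_input")
  }
  if (length(channels) != d[2] || anyDuplicated(channels)) {
    stop_vicarsep("channels must label each channel exactly once",
                  "vicarsep_invalid_input")
  }
  el <- unlist(analysis_electrodes())
  if (d[2] < 6L || !all(el %in% channels)) {
    stop_vicarsep("channels must include the six analysis electrodes 41,46,47,98,102,103",
                  "vicarsep_invalid_input")
  }
  if (length(condition) != d[1] || !all(condition %in% c("Hand", "Surface"))) {
    stop_vicarsep("condition must be 'Hand' or 'Surface' for every trial",
                  "vicarsep_invalid_input")
  }
  if (length(hand) != d[1] || !all(hand %in% c("Left", "Right"))) {
    stop_vicarsep("hand must be 'Left' or 'Right' for every trial",
                  "vicarsep_invalid_input")
  }
  if (!reference %in% c("vertex", "average")) {
    stop_vicarsep("reference must be 'vertex' or 'average'",
                  "vicarsep_invalid_input")
  }
  structure(
    list(data = data, time_ms = as.numeric(time_ms),
         condition = as.character(condition), hand = as.character(hand),
         channels = as.integer(channels),
         sampling_rate = as.numeric(sampling_rate),
         reference = reference,
         is_artifact = as.logical(is_artifact),
         participant_id = as.character(participant_id)),
    class = "epochset")
}

#' @export
print.epochset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Epoched EEG, participant %s\n", x$participant_id))
  cat(sprintf("  %d trials x %d channels x %d samples (%g-%g ms, %g Hz)\n",
              d[1], d[2], d[3], x$time_ms[1], x$time_ms[length(x$time_ms)],
              x$sampling_rate))
  cat(sprintf("  conditions: Hand %d, Surface %d; reference: %s; flagged artifacts: %d\n",
              sum(x$condition == "Hand"), sum(x$condition == "Surface"),
              x$reference, sum(x$is_artifact)))
  invisible(x)
}
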