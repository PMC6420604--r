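#' Single-channel ECoG recording
#'
#' Lightweight container for a one-channel voltage trace. The signal is stored
#' as a numeric vector (microvolts unless the recording has been min-max
#' scaled); everything derived from it downstream — state intervals, seizure
#' events, stimulation logs, features — is tabular (tibbles).
#'
#' @param samples Numeric vector of voltages (microvolts, or unitless after
#'   scaling).
#' @param sampling_rate Sampling rate in Hz (default 512).
#' @param animal_id Identifier of the (real or simulated) animal.
#' @param annotations Optional ground truth, a list with tibbles
#'   `state_intervals` (`start_s`, `end_s`, `state`), `seizure_events`
#'   (`onset_s`, `offset_s`, `duration_s`, ...) and `stim_events`.
#' @param scaled Logical; `TRUE` once [minmax_scale()] has been applied.
#'
#' @return An object of class `ecog_recording`.
#' @seealso [generate_recording()], [minmax_scale()], [read_ecog()]
#' @export
ecog_recording <- function(samples, sampling_rate = 512, animal_id = "a1",
                           annotations = NULL, scaled = FALSE) {
  if (!is.numeric(samples) || length(samples) < 1) {
    abort("`samples` must be a non-empty numeric vector.")
  }
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    abort("`sampling_rate` must be a positive number.")
  }
  if (any(!is.finite(samples))) abort("`samples` must be finite.")
  structure(
    list(
      samples = as.numeric(samples),
      sampling_rate = sampling_rate,
      duration = length(samples) / sampling_rate,
      animal_id = as.character(animal_id),
      annotations = annotations,
      scaled = isTRUE(scaled)
    ),
    class = "ecog_recording"
  )
}

#' @export
print.ecog_recording <- function(x, ...) {
  cat(sprintf(
    "<ecog_recording> %s: %.1f s at %g Hz (%d samples, %s)\n",
    x$animal_id, x$duration, x$sampling_rate, length(x$samples),
    if (x$scaled) "scaled [0,1]" else "microvolts"
  ))
  if (!is.null(x$annotations)) {
    gt <- x$annotations
    cat(sprintf(
      "  ground truth: %d state intervals, %d seizure events, %d stim events\n",
      nrow(gt$state_intervals %||% tibble()),
      nrow(gt$seizure_events %||% tibble()),
      nrow(gt$stim_events %||% tibble())
    ))
  }
  invisible(x)
}

#' Extract the state-interval / seizure-event / stimulation tables
#'
#' Accessors returning the ground-truth tibbles attached to a recording
#' (empty tibbles when absent).
#'
#' @param recording An [ecog_recording()].
#' @return A tibble.
#' @export
state_intervals <- function(recording) {
  recording$annotations$state_intervals %||%
    tibble(start_s = numeric(), end_s = numeric(), state = character())
}

#' @rdname state_intervals
#' @export
seizure_events <- function(recording) {
  recording$annotations$seizure_events %||%
    tibble(onset_s = numeric(), offset_s = numeric(), duration_s = numeric())
}

#' @rdname state_intervals
#' @export
stim_events <- function(recording) {
  recording$annotations$stim_events %||% empty_stim_log()
}

#' Network-state labels
#'
#' The four generator states plus the classifier-only `MIXED` label.
#' @return Character vector of state names.
#' @export
state_levels <- function() {
  c("BASELINE", "S1_INTERICTAL", "S2_ICTAL", "S3_CONTINUOUS")
}

#' @rdname state_levels
#' @export
mixed_label <- function() "MIXED"
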