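#' Stimulation scheduling policy
#'
#' Parameters of the simulated closed-loop controller: accepted trials must
#' be at least `min_interval` apart (>= 20 s, so that clean 10-s pre- and
#' post-stimulation epochs exist), trials alternate control / stimulated
#' starting with a control, delays of stimulated trials are sampled from
#' `delay_weights`, and light pulses last `light_duration` seconds.
#'
#' @param min_interval Minimum spacing between accepted trials, seconds
#'   (>= 20).
#' @param alternate Alternate control/stimulated trials (default `TRUE`).
#' @param delay_weights Named sampling weights over delay classes
#'   `"0"`, `"0.5"`, `"2"`, `">2"`.
#' @param light_duration Light pulse length, seconds (default 10).
#' @param long_delay_range Range (seconds) from which `">2"` delays are drawn
#'   uniformly; the default gives mean ~3.65 s.
#' @param warmup Stimulation-free lead-in at the start of a session, seconds.
#' @param mode `"triggered"` (delay classes per trial) or `"continuous"`
#'   (every accepted detection opens a 10-s light window affecting all
#'   discharges starting inside it).
#' @return A `scheduler_policy` list.
#' @export
scheduler_policy <- function(min_interval = 20, alternate = TRUE,
                             delay_weights = c("0" = 1, "0.5" = 1,
                                               "2" = 1, ">2" = 1),
                             light_duration = 10,
                             long_delay_range = c(2.5, 4.8),
                             warmup = 30,
                             mode = c("triggered", "continuous")) {
  if (min_interval < 20) {
    abort("`min_interval` must be >= 20 s (pre/post epoch collection).")
  }
  mode <- match.arg(mode)
  if (mode == "continuous") alternate <- FALSE
  structure(
    list(min_interval = min_interval, alternate = alternate,
         delay_weights = delay_weights, light_duration = light_duration,
         long_delay_range = long_delay_range, warmup = warmup, mode = mode),
    class = "scheduler_policy"
  )
}

#' Data-driven detection threshold
#'
#' Robust threshold for the online negative-going voltage detector:
#' `median - k * MAD` of a stimulation-free prefix of the recording (at
#' least 30 s). Median/MAD make the threshold insensitive to the occasional
#' seizure inside the prefix.
#'
#' @param recording A (scaled or raw) [ecog_recording()].
#' @param k MAD multiplier (default 6).
#' @param prefix_s Prefix length used, seconds (default 30; the recording
#'   must be at least this long).
#' @return Threshold in the recording's units.
#' @export
auto_threshold <- function(recording, k = 6, prefix_s = 30) {
  stopifnot(inherits(recording, "ecog_recording"))
  n <- round(prefix_s * recording$sampling_rate)
  if (length(recording$samples) < n) {
    abort(sprintf("Need at least %g s of recording for auto_threshold.",
                  prefix_s))
  }
  x <- recording$samples[seq_len(n)]
  median(x) - k * mad(x)
}

#' Online seizure-onset detection by threshold crossing
#'
#' Causal negative-going threshold detector emulating the FPGA path: a
#' detection is raised at the first sample crossing `threshold` downward.
#' Every crossing (detected or not) re-arms the dead time, so a detection
#' fires only after the signal has stayed above threshold for a full
#' `refractory` period — an ongoing discharge, whose body spikes keep
#' crossing the threshold, therefore cannot retrigger, and the next
#' sentinel after a quiet gap is caught. The large negative sentinel spike
#' at seizure onset makes this an onset detector. Causal: truncating the
#' recording never changes earlier detections.
#'
#' @param recording An [ecog_recording()].
#' @param threshold Crossing threshold in the recording's units (typically
#'   from [auto_threshold()]).
#' @param refractory Required quiet time since the last crossing, seconds
#'   (default 0.4: longer than one discharge-spike period, shorter than any
#'   inter-event gap).
#' @return A tibble with `detection_time_s`.
#' @export
detect_onsets <- function(recording, threshold, refractory = 0.4) {
  stopifnot(inherits(recording, "ecog_recording"))
  if (refractory < 0) abort("`refractory` must be >= 0.")
  x <- recording$samples
  below <- x < threshold
  cross <- which(below & !c(FALSE, below[-length(below)]))
  if (!length(cross)) return(tibble(detection_time_s = numeric()))
  fs <- recording$sampling_rate
  tcross <- (cross - 1) / fs
  gap_ok <- c(TRUE, diff(tcross) >= refractory)
  tibble(detection_time_s = tcross[gap_ok])
}

#' Schedule stimulation trials from detection times
#'
#' Pure scheduler logic, for replaying or testing the closed-loop rules:
#' detections closer than `min_interval` to the previous accepted trial are
#' skipped; accepted trials alternate control (no light) / stimulated,
#' starting with a control; stimulated trials draw a delay class from the
#' policy weights (the `">2"` class draws its realized delay uniformly from
#' `long_delay_range`).
#'
#' @param detections Tibble with `detection_time_s` (sorted ascending) or a
#'   numeric vector.
#' @param policy A [scheduler_policy()].
#' @param seed Integer seed for delay sampling.
#' @param condition Condition name recorded in the log.
#' @return A stimulation-log tibble (see [run_closed_loop_session()]).
#' @export
schedule_stimulations <- function(detections, policy = scheduler_policy(),
                                  seed = 1, condition = "NO_OPSIN") {
  d <- if (is.data.frame(detections)) detections$detection_time_s else
    as.numeric(detections)
  if (is.unsorted(d)) abort("`detections` must be sorted ascending.")
  withr::with_seed(seed, {
    rows <- list()
    last <- -Inf
    next_control <- TRUE
    for (t in d) {
      if (t - last < policy$min_interval) next
      last <- t
      sid <- length(rows) + 1L
      if (policy$alternate && next_control) {
        rows[[sid]] <- tibble(
          stim_id = sid, detection_time_s = t, delay_s = NA_real_,
          delay_class = NA_character_, light_on_s = NA_real_,
          light_duration_s = policy$light_duration, triggered = FALSE,
          condition = condition
        )
        next_control <- FALSE
      } else {
        w <- policy$delay_weights
        cls <- sample(names(w), 1, prob = w)
        del <- switch(cls, "0" = 0, "0.5" = 0.5, "2" = 2,
                      ">2" = runif(1, policy$long_delay_range[1],
                                   policy$long_delay_range[2]))
        rows[[sid]] <- tibble(
          stim_id = sid, detection_time_s = t, delay_s = del,
          delay_class = cls, light_on_s = t + del,
          light_duration_s = policy$light_duration, triggered = TRUE,
          condition = condition
        )
        if (policy$alternate) next_control <- TRUE
      }
    }
    if (length(rows)) bind_rows(rows) else empty_stim_log()
  })
}

#' Simulate one closed-loop stimulation session
#'
#' Generates a State-2 session under `profile`, runs the closed-loop
#' controller inside the generator (detection at the sentinel, alternate
#' control/stimulated trials at least `min_interval` apart, randomized
#' delays) and applies the profile's duration effect to every stimulated
#' event. The returned ground truth records, for each stimulated trial, the
#' realized and the counterfactual (control) duration.
#'
#' @inheritParams generate_recording
#' @param policy A [scheduler_policy()].
#' @return A list of class `closed_loop_session`: `recording` (with ground
#'   truth) and `stim_log`.
#' @export
run_closed_loop_session <- function(profile, policy = scheduler_policy(),
                                    duration = 1800, seed = 1,
                                    animal_id = "a1",
                                    params = seizure_waveform_params(),
                                    decoy_prob = 0.3) {
  rec <- generate_recording(profile, duration, seed, animal_id = animal_id,
                            params = params, policy = policy,
                            decoy_prob = decoy_prob)
  structure(list(recording = rec, stim_log = stim_events(rec)),
            class = "closed_loop_session")
}

#' @export
print.closed_loop_session <- function(x, ...) {
  s <- x$stim_log
  cat(sprintf(
    "<closed_loop_session> %s: %.0f s, %d trials (%d stimulated)\n",
    x$recording$animal_id, x$recording$duration, nrow(s), sum(s$triggered)
  ))
  invisible(x)
}

#' Simulate a cohort of closed-loop sessions
#'
#' Runs one session per animal with per-animal sub-seeds derived from the
#' master seed, and mild animal-to-animal variation in baseline seizure
#' duration (mean-one lognormal factor, log-sd 0.08) and noise amplitude
#' (+-15%), emulating between-animal heterogeneity.
#'
#' @inheritParams run_closed_loop_session
#' @param n_animals Number of simulated animals.
#' @param seed Master seed; per-animal seeds derive from it.
#' @return A list of `closed_loop_session` objects named by animal id.
#' @export
simulate_cohort <- function(profile, n_animals, policy = scheduler_policy(),
                            duration = 900, seed = 1,
                            params = seizure_waveform_params(),
                            decoy_prob = 0.3) {
  lapply(setNames(seq_len(n_animals),
                  sprintf("m%02d", seq_len(n_animals))), function(a) {
    aseed <- derive_seed(seed, a)
    withr::with_seed(derive_seed(aseed, 999), {
      f_dur <- exp(rnorm(1, 0, 0.08) - 0.08^2 / 2)
      f_noise <- runif(1, 0.85, 1.15)
    })
    prof_a <- profile
    prof_a$control_duration_mean_by_delay <-
      profile$control_duration_mean_by_delay * f_dur
    par_a <- params
    par_a$baseline_noise_sd <- params$baseline_noise_sd * f_noise
    run_closed_loop_session(prof_a, policy, duration, aseed,
                            animal_id = sprintf("m%02d", a),
                            params = par_a, decoy_prob = decoy_prob)
  })
}
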