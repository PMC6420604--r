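empty_stim_log <- function() {
  tibble(
    stim_id = integer(), detection_time_s = numeric(), delay_s = numeric(),
    delay_class = character(), light_on_s = numeric(),
    light_duration_s = numeric(), triggered = logical(), condition = character()
  )
}

empty_event_table <- function() {
  tibble(
    event_id = integer(), onset_s = numeric(), offset_s = numeric(),
    duration_s = numeric(), role = character(), counterfactual_s = numeric(),
    stim_id = integer(), animal_id = character()
  )
}

# Sequential construction of one State-2 event stream on [t0, t1], optionally
# driving a closed-loop stimulation schedule. Runs in the ambient RNG stream.
#
# Event log-durations carry a slowly varying sinusoidal component (random
# phase, period `slow_period_events` events) plus fast iid jitter
# (`fast_jitter_sd`), with marginal log-sd equal to the profile dispersion.
# Consecutive events are thereby strongly correlated, which is what makes the
# paired ratio estimator (stimulated / immediately preceding control) centred
# on the programmed multiplier. The slow component advances per event, not
# per second: long-duration stretches host fewer onsets per unit time, so a
# time-indexed drift would make the realized event sample length-biased below
# the configured mean, while an event-indexed drift weights all phases
# equally and keeps the sample mean at the lognormal mean.
#
# For stimulated trials the base duration D is drawn by draw_control_duration
# (truncated below the realized delay for delayed classes); the immediately
# preceding event is overridden to D*exp(e1) and the stimulated event set to
# multiplier*D*exp(e2) (e ~ N(0, pair_jitter_sd)), so the programmed effect is
# identifiable by the paired analysis. With probability `decoy_prob` a
# delayed-class trial gets a short (< delay) decoy event inserted between
# control and stimulated event, exercising the control-substitution rule.
build_event_schedule <- function(t0, t1, profile, policy = NULL,
                                 base_mean = NULL,
                                 decoy_prob = 0.3,
                                 fast_jitter_sd = 0.15,
                                 pair_jitter_sd = 0.1,
                                 slow_period_events = 64,
                                 slow_phase = NULL,
                                 idx_offset = 0) {
  sigma <- profile$duration_dispersion
  continuous <- !is.null(policy) && isTRUE(policy$mode == "continuous")
  if (is.null(base_mean)) {
    base_mean <- profile$control_duration_mean_by_delay[[
      if (continuous) "continuous" else "0"]]
  }
  amp <- sqrt(max(0, 2 * (sigma^2 - fast_jitter_sd^2)))
  phase <- slow_phase %||% runif(1, 0, 2 * pi)
  mu <- log(base_mean) - sigma^2 / 2
  gmean <- max(0.2, 1 / profile$seizure_rate - base_mean - 0.5)

  onset <- dur <- cf <- gapv <- numeric(0)
  role <- character(0)
  ev_stim <- integer(0)
  stim_rows <- list()
  n <- 0L
  last_accept <- -Inf
  next_control <- TRUE
  light_end <- -Inf
  light_stim_id <- NA_integer_
  warmup <- if (!is.null(policy)) max(20, policy$warmup) else 0
  cont_mult <- profile$duration_multiplier_by_delay[["continuous"]]
  end_prev <- t0

  repeat {
    gap <- 0.5 + rexp(1, 1 / gmean)
    o <- end_prev + gap
    if (o + 1 > t1) break
    slow <- amp * sin(2 * pi * (idx_offset + n + 1) / slow_period_events +
                        phase)
    d <- exp(mu + slow + rnorm(1, 0, fast_jitter_sd))
    n <- n + 1L
    onset[n] <- o; dur[n] <- d; gapv[n] <- gap
    role[n] <- "free"; cf[n] <- NA_real_; ev_stim[n] <- NA_integer_

    if (!is.null(policy)) {
      accepted <- o >= t0 + warmup && (o - last_accept) >= policy$min_interval
      if (continuous) {
        if (accepted) {
          last_accept <- o
          light_end <- o + policy$light_duration
          sid <- length(stim_rows) + 1L
          light_stim_id <- sid
          stim_rows[[sid]] <- list(
            stim_id = sid, detection_time_s = o, delay_s = 0,
            delay_class = "continuous", light_on_s = o,
            light_duration_s = policy$light_duration, triggered = TRUE,
            condition = profile$name
          )
        }
        if (onset[n] < light_end) {
          cf[n] <- dur[n]
          dur[n] <- dur[n] * cont_mult
          role[n] <- "stim_window"
          ev_stim[n] <- light_stim_id
        }
      } else if (accepted && policy$alternate && next_control) {
        role[n] <- "control_trial"
        next_control <- FALSE
        last_accept <- o
        sid <- length(stim_rows) + 1L
        stim_rows[[sid]] <- list(
          stim_id = sid, detection_time_s = o, delay_s = NA_real_,
          delay_class = NA_character_, light_on_s = NA_real_,
          light_duration_s = policy$light_duration, triggered = FALSE,
          condition = profile$name
        )
        ev_stim[n] <- sid
      } else if (accepted &&
                 n >= 2L && !role[n - 1L] %in% c("stim", "stim_window")) {
        w <- policy$delay_weights
        cls <- sample(names(w), 1, prob = w)
        del <- switch(cls,
          "0" = 0, "0.5" = 0.5, "2" = 2,
          ">2" = runif(1, policy$long_delay_range[1], policy$long_delay_range[2])
        )
        d_base <- draw_control_duration(cls, profile, delay = del)
        use_decoy <- cls %in% c("2", ">2") && n >= 3L &&
          role[n - 1L] == "free" && role[n - 2L] == "free" &&
          runif(1) < decoy_prob
        if (use_decoy) {
          dur[n - 2L] <- d_base * exp(rnorm(1, 0, pair_jitter_sd))
          role[n - 2L] <- "control"
          dur[n - 1L] <- runif(1, 0.8, max(0.95, 0.7 * del))
          role[n - 1L] <- "decoy"
          onset[n - 1L] <- onset[n - 2L] + dur[n - 2L] + gapv[n - 1L]
        } else {
          dur[n - 1L] <- d_base * exp(rnorm(1, 0, pair_jitter_sd))
          if (role[n - 1L] == "free") role[n - 1L] <- "control"
        }
        onset[n] <- onset[n - 1L] + dur[n - 1L] + gapv[n]
        # overriding durations moved this onset; re-check the trial window
        if (onset[n] + 1 > t1) { n <- n - 1L; break }
        if (onset[n] - last_accept >= policy$min_interval) {
          scale <- exp(rnorm(1, 0, pair_jitter_sd))
          cf[n] <- d_base * scale
          dur[n] <- apply_stimulation_effect(d_base, cls, profile) * scale
          role[n] <- "stim"
          last_accept <- onset[n]
          if (policy$alternate) next_control <- TRUE
          sid <- length(stim_rows) + 1L
          stim_rows[[sid]] <- list(
            stim_id = sid, detection_time_s = onset[n], delay_s = del,
            delay_class = cls, light_on_s = onset[n] + del,
            light_duration_s = policy$light_duration, triggered = TRUE,
            condition = profile$name
          )
          ev_stim[n] <- sid
        }
      }
    }
    end_prev <- onset[n] + dur[n]
  }

  # drop trailing events that overrun the interval
  while (n > 0L && onset[n] + dur[n] > t1 - 0.05) {
    if (!is.na(ev_stim[n]) && role[n] %in% c("stim", "control_trial")) {
      stim_rows[[ev_stim[n]]] <- NULL
    }
    n <- n - 1L
  }
  keep <- seq_len(n)
  events <- tibble(
    onset_s = onset[keep], duration_s = dur[keep],
    offset_s = onset[keep] + dur[keep], role = role[keep],
    counterfactual_s = cf[keep], stim_id = ev_stim[keep]
  )
  stim <- if (length(stim_rows)) {
    bind_rows(lapply(stim_rows, function(r) tibble::as_tibble(r)))
  } else {
    empty_stim_log()
  }
  list(events = events, stim = stim, n_events = n)
}

#' Generate a synthetic ECoG recording with ground truth
#'
#' Seeded generator emulating pilocarpine-induced focal cortical activity:
#' quiescent baseline, brief interictal bursts (State 1), discrete seizures
#' with a negative sentinel spike and a high-frequency body (State 2), and
#' continuous epileptiform activity (State 3), on a 1/f noise background.
#' Identical `(profile, duration, seed, ...)` give bit-identical samples and
#' ground truth.
#'
#' Without a `policy`, the recording is tiled with state segments drawn from
#' `state_mix` (for classifier training/testing material). With a `policy`
#' (see [scheduler_policy()]), the recording is a closed-loop session: a
#' baseline lead-in followed by State-2 activity in which stimulation trials
#' are scheduled and the profile's duration effects are applied to the
#' stimulated events; the ground truth then records, for every stimulated
#' trial, the realized and counterfactual control durations.
#'
#' @param profile A [condition_profile()].
#' @param duration Recording length in seconds (> 0).
#' @param seed Integer seed.
#' @param animal_id Identifier stored in the recording and its event table.
#' @param state_mix Named probabilities over
#'   `BASELINE, S1_INTERICTAL, S2_ICTAL, S3_CONTINUOUS` for free recordings.
#' @param params A [seizure_waveform_params()].
#' @param policy Optional [scheduler_policy()] for closed-loop sessions.
#' @param decoy_prob Probability of inserting a short decoy event before a
#'   delayed-class stimulated event (exercises the control-substitution rule).
#' @return An [ecog_recording()] with complete ground-truth annotations.
#' @examples
#' rec <- generate_recording(condition_profile("NO_OPSIN"), 120, seed = 1)
#' rec
#' @export
generate_recording <- function(profile, duration, seed,
                               animal_id = "a1",
                               state_mix = c(BASELINE = 0.25,
                                             S1_INTERICTAL = 0.25,
                                             S2_ICTAL = 0.35,
                                             S3_CONTINUOUS = 0.15),
                               params = seizure_waveform_params(),
                               policy = NULL,
                               decoy_prob = 0.3) {
  if (!is.numeric(duration) || duration <= 0) {
    abort("`duration` must be a positive number of seconds.")
  }
  stopifnot(inherits(profile, "condition_profile"))
  fs <- 512
  withr::with_seed(seed, {
    n <- max(1L, round(duration * fs))
    x <- pink_noise(n, params$baseline_noise_sd)

    # ---- state layout ----
    if (!is.null(policy)) {
      lead <- min(20, duration / 2)
      ivs <- tibble(
        start_s = c(0, lead), end_s = c(lead, duration),
        state = c("BASELINE", "S2_ICTAL")
      )
      ivs <- ivs[ivs$end_s > ivs$start_s, ]
    } else if (duration < 30) {
      st <- if (duration < 12) "BASELINE" else
        sample(names(state_mix), 1, prob = state_mix)
      ivs <- tibble(start_s = 0, end_s = duration, state = st)
    } else {
      starts <- 0
      while (tail(starts, 1) < duration) {
        starts <- c(starts, tail(starts, 1) + runif(1, 30, 60))
      }
      starts <- head(starts, -1)
      ivs <- tibble(
        start_s = starts,
        end_s = c(starts[-1], duration),
        state = sample(names(state_mix), length(starts),
                       replace = TRUE, prob = state_mix)
      )
    }

    all_events <- list()
    stim_log <- empty_stim_log()
    # one slow-drift phase for the whole recording, and a running event
    # index, so durations stay continuous across State-2 segments
    slow_phase <- runif(1, 0, 2 * pi)
    idx_offset <- 0
    add_wave <- function(x, wv, at_s) {
      i0 <- round(at_s * fs) + 1L
      if (i0 > length(x)) return(x)
      idx <- i0:min(length(x), i0 + length(wv) - 1L)
      x[idx] <- x[idx] + wv[seq_along(idx)]
      x
    }

    for (k in seq_len(nrow(ivs))) {
      st <- ivs$state[k]; a <- ivs$start_s[k]; b <- ivs$end_s[k]
      if (st == "S2_ICTAL") {
        sched <- build_event_schedule(a, b, profile, policy = policy,
                                      decoy_prob = decoy_prob,
                                      slow_phase = slow_phase,
                                      idx_offset = idx_offset)
        idx_offset <- idx_offset + sched$n_events
        ev <- sched$events
        for (j in seq_len(nrow(ev))) {
          wv <- generate_seizure_waveform(ev$duration_s[j], params, fs)
          x <- add_wave(x, wv, ev$onset_s[j])
        }
        all_events[[length(all_events) + 1L]] <- ev
        stim_log <- bind_rows(stim_log, sched$stim)
      } else if (st == "S1_INTERICTAL") {
        t <- a + rexp(1, 1 / 2)
        while (t < b - 0.2) {
          len <- runif(1, params$burst_len_range[1], params$burst_len_range[2])
          x <- add_wave(x, burst_waveform(len, params, fs), t)
          t <- t + 0.4 + rexp(1, 1 / 1.8)
        }
      } else if (st == "S3_CONTINUOUS") {
        x <- add_wave(x, continuous_activity(b - a, params, fs), a)
      }
    }

    events <- if (length(all_events)) bind_rows(all_events) else
      empty_event_table()[, c("onset_s", "duration_s", "offset_s", "role",
                              "counterfactual_s", "stim_id")]
    events$animal_id <- as.character(animal_id)
    events$event_id <- seq_len(nrow(events))
    ecog_recording(
      samples = x, sampling_rate = fs, animal_id = animal_id,
      annotations = list(
        state_intervals = ivs,
        seizure_events = events[, c("event_id", "onset_s", "offset_s",
                                    "duration_s", "role", "counterfactual_s",
                                    "stim_id", "animal_id")],
        stim_events = stim_log
      )
    )
  })
}
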