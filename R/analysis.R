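#' Offline event segmentation
#'
#' Segments epileptiform discharges from a (scaled) recording: an event
#' starts at a downward crossing of `threshold` and ends when no
#' suprathreshold deflection occurs for `min_gap` seconds; clusters closer
#' than `min_gap` are merged and events shorter than `min_duration` are
#' discarded. The default threshold is `median - k_mad * sigma`, with
#' `sigma` a noise-floor estimate taken from the positive deviations only
#' (epileptiform deflections are negative-going, so the positive side is
#' dominated by noise even in recordings that are mostly ictal); it sits
#' below the online detection threshold, so that the repetitive discharge
#' spikes of a seizure body keep the event alive.
#'
#' @param recording An [ecog_recording()]; scaled internally if needed.
#' @param threshold Segmentation threshold (scaled units); `NULL` for the
#'   default above.
#' @param k_mad Noise-sigma multiplier for the default threshold (default 4).
#' @param min_gap Maximum subthreshold gap inside one event, seconds.
#' @param min_duration Minimum event duration, seconds.
#' @return A tibble: `event_id`, `onset_s`, `offset_s`, `duration_s`,
#'   `animal_id`.
#' @export
segment_events <- function(recording, threshold = NULL, k_mad = 4,
                           min_gap = 0.3, min_duration = 0.5) {
  stopifnot(inherits(recording, "ecog_recording"))
  if (!recording$scaled) recording <- minmax_scale(recording)
  x <- recording$samples
  if (is.null(threshold)) {
    med <- median(x)
    pos <- x[x > med] - med
    sigma <- if (length(pos)) median(pos) / 0.6745 else 0
    threshold <- med - k_mad * sigma
  }
  idx <- which(x < threshold)
  if (!length(idx)) {
    return(tibble(event_id = integer(), onset_s = numeric(),
                  offset_s = numeric(), duration_s = numeric(),
                  animal_id = character()))
  }
  fs <- recording$sampling_rate
  t <- (idx - 1) / fs
  grp <- cumsum(c(1, diff(t) > min_gap))
  onset <- as.numeric(tapply(t, grp, min))
  offset <- as.numeric(tapply(t, grp, max)) + 1 / fs
  keep <- (offset - onset) >= min_duration
  tibble(
    event_id = seq_len(sum(keep)),
    onset_s = onset[keep],
    offset_s = offset[keep],
    duration_s = offset[keep] - onset[keep],
    animal_id = recording$animal_id
  )
}

# Attach to each stimulation row the id of the event containing its
# detection time (NA when no event matches within `tol` seconds).
link_stim_to_events <- function(events, stim_log, tol = 0.1) {
  if (!nrow(stim_log)) return(mutate(stim_log, event_id = integer()))
  ev_id <- vapply(stim_log$detection_time_s, function(d) {
    if (is.na(d)) return(NA_integer_)
    hit <- which(events$onset_s - tol <= d & d <= events$offset_s)
    if (length(hit)) events$event_id[hit[1]] else NA_integer_
  }, integer(1))
  mutate(stim_log, event_id = ev_id)
}

#' Pair stimulated seizures with preceding controls
#'
#' Implements the paired-trial rule of the closed-loop analysis: each
#' triggered stimulation is linked to the event that caused detection; its
#' control is the immediately preceding non-stimulated event, except that a
#' control must outlast the programmed delay — when the immediate candidate
#' is shorter than the delay, the nearest preceding discharge exceeding the
#' delay is substituted. Trials failing the pre-stimulation gate (when
#' `stim_log` carries a `gate_pass` column, e.g. from
#' [gate_pre_stimulation()]) and trials without any qualifying control are
#' dropped.
#'
#' @param events Event tibble from [segment_events()] (sorted by onset).
#' @param stim_log Stimulation log tibble.
#' @return A tibble of trial pairs: ids, durations, `delay_class`,
#'   `condition` and `normalized_pct` (100 x stimulated / control). Dropped
#'   trials are recorded in the `"dropped"` attribute with a reason.
#' @export
pair_trials <- function(events, stim_log) {
  events <- arrange(events, .data$onset_s)
  stim_log <- link_stim_to_events(events, stim_log)
  trig <- filter(stim_log, .data$triggered)
  if ("gate_pass" %in% names(trig)) {
    dropped_gate <- filter(trig, !.data$gate_pass)
    trig <- filter(trig, .data$gate_pass)
  } else {
    dropped_gate <- trig[0, ]
  }
  stim_event_ids <- stim_log$event_id[stim_log$triggered]
  pairs <- list()
  dropped <- list()
  if (nrow(dropped_gate)) {
    dropped[[1]] <- tibble(stim_id = dropped_gate$stim_id,
                           reason = "gate: pre-epoch not confident State 2")
  }
  for (i in seq_len(nrow(trig))) {
    s <- trig[i, ]
    if (is.na(s$event_id)) {
      dropped[[length(dropped) + 1]] <-
        tibble(stim_id = s$stim_id, reason = "no event at detection time")
      next
    }
    sev <- events[events$event_id == s$event_id, ]
    cand <- events[events$onset_s < sev$onset_s &
                     !(events$event_id %in% stim_event_ids), ]
    delay <- if (is.na(s$delay_s)) 0 else s$delay_s
    cand <- cand[cand$duration_s > delay, ]
    if (!nrow(cand)) {
      dropped[[length(dropped) + 1]] <-
        tibble(stim_id = s$stim_id,
               reason = "no qualifying preceding control")
      next
    }
    ctrl <- cand[which.max(cand$onset_s), ]
    pairs[[length(pairs) + 1]] <- tibble(
      stim_id = s$stim_id,
      animal_id = sev$animal_id,
      condition = s$condition,
      delay_class = s$delay_class,
      delay_s = s$delay_s,
      stim_event_id = sev$event_id,
      control_event_id = ctrl$event_id,
      stim_duration_s = sev$duration_s,
      control_duration_s = ctrl$duration_s,
      normalized_pct = 100 * sev$duration_s / ctrl$duration_s
    )
  }
  out <- if (length(pairs)) bind_rows(pairs) else tibble(
    stim_id = integer(), animal_id = character(), condition = character(),
    delay_class = character(), delay_s = numeric(),
    stim_event_id = integer(), control_event_id = integer(),
    stim_duration_s = numeric(), control_duration_s = numeric(),
    normalized_pct = numeric()
  )
  attr(out, "dropped") <- if (length(dropped)) bind_rows(dropped) else
    tibble(stim_id = integer(), reason = character())
  out
}

#' Normalized seizure duration of a trial pair
#'
#' 100 x stimulated duration / control duration, in percent.
#'
#' @param stim_duration_s,control_duration_s Durations in seconds.
#' @return Percent.
#' @export
normalized_duration <- function(stim_duration_s, control_duration_s) {
  if (any(control_duration_s <= 0)) abort("Control duration must be > 0.")
  100 * stim_duration_s / control_duration_s
}

#' Pre / during / post light-window analysis
#'
#' Assigns events to the 10-s windows before, during and after each light
#' pulse (an event belongs to a window when its onset falls inside it),
#' computes per-animal mean durations and event counts per window, then the
#' group mean +- s.e.m. over animals.
#'
#' @param events Event tibble (one or more animals).
#' @param stim_log Stimulation log with triggered trials carrying
#'   `light_on_s` and `light_duration_s`.
#' @param window_s Window length, seconds (default 10).
#' @return A `window_result`: list with `per_animal` and `summary` tibbles.
#' @export
window_analysis <- function(events, stim_log, window_s = 10) {
  trig <- filter(stim_log, .data$triggered, !is.na(.data$light_on_s))
  rows <- list()
  for (i in seq_len(nrow(trig))) {
    L <- trig$light_on_s[i]
    D <- trig$light_duration_s[i]
    win <- tibble(
      window = c("pre", "during", "post"),
      a = c(L - window_s, L, L + D),
      b = c(L, L + D, L + D + window_s)
    )
    for (j in 1:3) {
      sel <- events[events$onset_s >= win$a[j] & events$onset_s < win$b[j], ]
      rows[[length(rows) + 1]] <- tibble(
        animal_id = if (nrow(sel)) sel$animal_id[1] else
          events$animal_id[1] %||% NA_character_,
        stim_id = trig$stim_id[i], window = win$window[j],
        n_events = nrow(sel),
        mean_duration_s = if (nrow(sel)) mean(sel$duration_s) else NA_real_
      )
    }
  }
  per_trial <- bind_rows(rows)
  per_animal <- per_trial %>%
    group_by(.data$animal_id, .data$window) %>%
    summarise(
      mean_duration_s = mean(.data$mean_duration_s, na.rm = TRUE),
      rate_hz = sum(.data$n_events) / (n() * window_s),
      n_events = sum(.data$n_events),
      .groups = "drop"
    )
  summary <- per_animal %>%
    group_by(.data$window) %>%
    summarise(
      mean_duration_s = mean(.data$mean_duration_s, na.rm = TRUE),
      sem_duration_s = sd(.data$mean_duration_s, na.rm = TRUE) /
        sqrt(sum(!is.na(.data$mean_duration_s))),
      mean_rate_hz = mean(.data$rate_hz),
      n_animals = n(),
      .groups = "drop"
    ) %>%
    mutate(window = factor(.data$window, c("pre", "during", "post"))) %>%
    arrange(.data$window)
  structure(list(per_animal = per_animal, summary = summary),
            class = "window_result")
}

#' @export
print.window_result <- function(x, ...) {
  cat("<window_result>\n")
  print(x$summary)
  invisible(x)
}

#' Reshuffled pseudo-stimulation null
#'
#' Estimates the no-effect distribution of normalized duration while
#' deliberately ignoring all stimulation information: events longer than
#' `eligible_min` (2.5 s) are randomly assigned to the pseudo-stimulated
#' group; each pseudo-stimulated event is compared to the immediately
#' preceding event, and if that event is shorter than `qualify_min` (3 s)
#' the closest preceding qualifying event (duration >= 3 s) is used instead.
#' Pseudo-trials without a qualifying control are dropped.
#'
#' @param events Event tibble for one animal (or with an `animal_id`
#'   column).
#' @param seed Integer seed for the random assignment.
#' @param eligible_min Minimum duration for pseudo-stimulated events (s).
#' @param qualify_min Minimum duration of a qualifying control (s).
#' @param p_select Probability that an eligible event is assigned to the
#'   pseudo-stimulated group.
#' @return A trial-pair tibble in the same shape as [pair_trials()] (with
#'   `delay_class = "pseudo"`).
#' @export
reshuffle_null <- function(events, seed = 1, eligible_min = 2.5,
                           qualify_min = 3, p_select = 0.5) {
  events <- arrange(events, .data$onset_s)
  withr::with_seed(seed, {
    sel <- which(events$duration_s > eligible_min &
                   runif(nrow(events)) < p_select)
    pairs <- list()
    for (i in sel) {
      if (i < 2) next
      j <- i - 1
      if (events$duration_s[j] < qualify_min) {
        prev <- which(events$duration_s[seq_len(i - 1)] >= qualify_min)
        if (!length(prev)) next
        j <- max(prev)
      }
      pairs[[length(pairs) + 1]] <- tibble(
        stim_id = NA_integer_,
        animal_id = events$animal_id[i],
        condition = "pseudo",
        delay_class = "pseudo",
        delay_s = NA_real_,
        stim_event_id = events$event_id[i],
        control_event_id = events$event_id[j],
        stim_duration_s = events$duration_s[i],
        control_duration_s = events$duration_s[j],
        normalized_pct = 100 * events$duration_s[i] / events$duration_s[j]
      )
    }
    if (length(pairs)) bind_rows(pairs) else
      pair_trials(events[0, ], empty_stim_log())
  })
}

#' Per-animal aggregation of trial pairs
#'
#' Trial-level normalized durations are averaged within animal before any
#' group statistic, so every animal carries equal weight regardless of its
#' trial count.
#'
#' @param pairs A trial-pair tibble.
#' @return A tibble: `animal_id`, `mean_normalized_pct`,
#'   `mean_stim_duration_s`, `mean_control_duration_s`, `n_trials`.
#' @export
per_animal_aggregate <- function(pairs) {
  pairs %>%
    group_by(.data$animal_id) %>%
    summarise(
      mean_normalized_pct = mean(.data$normalized_pct),
      mean_stim_duration_s = mean(.data$stim_duration_s),
      mean_control_duration_s = mean(.data$control_duration_s),
      n_trials = n(),
      .groups = "drop"
    )
}

#' Group-level normalized-duration result
#'
#' Aggregates trial pairs per animal, reports the group mean +- s.e.m. of
#' the normalized duration over animals, and tests stimulated against
#' control per-animal mean durations with a two-tailed paired t-test.
#'
#' @param pairs A trial-pair tibble (one condition / delay class).
#' @return A `group_result` object.
#' @export
group_normalized_duration <- function(pairs) {
  if (!nrow(pairs)) abort("No trial pairs.")
  pa <- per_animal_aggregate(pairs)
  tt <- if (nrow(pa) >= 2) {
    paired_t(pa$mean_stim_duration_s, pa$mean_control_duration_s)
  } else {
    tibble(t = NA_real_, df = NA_real_, p = NA_real_, degenerate = TRUE)
  }
  structure(
    list(
      per_animal = pa,
      mean_pct = mean(pa$mean_normalized_pct),
      sem_pct = sd(pa$mean_normalized_pct) / sqrt(nrow(pa)),
      n_animals = nrow(pa),
      n_trials = sum(pa$n_trials),
      test = "two-tailed paired t-test",
      statistic = tt$t, df = tt$df, p_value = tt$p,
      degenerate = tt$degenerate
    ),
    class = "group_result"
  )
}

#' @export
print.group_result <- function(x, ...) {
  cat(sprintf(
    "<group_result> normalized duration %.1f +- %.1f%% (%d trials in %d animals)\n",
    x$mean_pct, x$sem_pct, x$n_trials, x$n_animals
  ))
  if (!isTRUE(x$degenerate)) {
    cat(sprintf("  %s: t(%g) = %.2f, p = %.3g\n", x$test, x$df, x$statistic,
                x$p_value))
  }
  invisible(x)
}

#' @rdname tidy
#' @export
tidy.group_result <- function(x, ...) x$per_animal

#' @rdname tidy
#' @export
glance.group_result <- function(x, ...) {
  tibble(
    mean_pct = x$mean_pct, sem_pct = x$sem_pct, n_animals = x$n_animals,
    n_trials = x$n_trials, statistic = x$statistic, df = x$df,
    p_value = x$p_value
  )
}

#' Two-tailed paired t-test
#'
#' Standard paired t on equal-length vectors paired by animal. All-zero
#' differences return `t = 0, p = 1`; nonzero constant differences (zero
#' variance) are flagged degenerate.
#'
#' @param a,b Paired numeric vectors (length >= 2).
#' @return One-row tibble: `t`, `df`, `p`, `degenerate`.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) abort("Paired vectors must have equal length.")
  if (length(a) < 2) abort("Need at least 2 pairs.")
  d <- a - b
  if (sd(d) == 0) {
    if (all(d == 0)) {
      return(tibble(t = 0, df = length(a) - 1, p = 1, degenerate = FALSE))
    }
    return(tibble(t = sign(d[1]) * Inf, df = length(a) - 1, p = NA_real_,
                  degenerate = TRUE))
  }
  tt <- t.test(a, b, paired = TRUE)
  tibble(t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, degenerate = FALSE)
}

#' One-way repeated-measures ANOVA with Bonferroni post hoc
#'
#' Compares per-animal means across the three light windows (or any within-
#' subject factor) with a one-way repeated-measures ANOVA (subject as the
#' error stratum) followed by pairwise paired t-tests with Bonferroni
#' correction (p multiplied by the number of comparisons, capped at 1).
#' Requires complete cases: every animal must have a value in every window.
#'
#' @param data Data frame with one row per animal x level.
#' @param value,within,subject Column names (strings) of the response, the
#'   within-subject factor and the subject id.
#' @return An `rm_anova` list: `F`, `df1`, `df2`, `p`, `posthoc` tibble.
#' @export
rm_anova_bonferroni <- function(data, value = "mean_duration_s",
                                within = "window", subject = "animal_id") {
  df <- data.frame(
    y = data[[value]],
    w = factor(data[[within]]),
    s = factor(data[[subject]])
  )
  tab <- table(df$s, df$w)
  if (any(tab != 1) || anyNA(df$y)) {
    abort("Incomplete design: every subject needs exactly one value per level.")
  }
  fit <- aov(y ~ w + Error(s), data = df)
  s2 <- summary(fit)[["Error: Within"]][[1]]
  rownames(s2) <- trimws(rownames(s2))
  Fv <- s2["w", "F value"]
  df1 <- s2["w", "Df"]
  df2 <- s2["Residuals", "Df"]
  p <- s2["w", "Pr(>F)"]
  # no within-subject variation at all (up to rounding): no effect
  total_ss <- sum((df$y - mean(df$y))^2)
  if (!is.finite(Fv) ||
      s2["w", "Sum Sq"] + s2["Residuals", "Sum Sq"] < 1e-10 * max(1, total_ss)) {
    Fv <- 0
    p <- 1
  }
  lev <- levels(df$w)
  cmb <- utils::combn(lev, 2)
  m <- ncol(cmb)
  posthoc <- bind_rows(lapply(seq_len(m), function(k) {
    a <- df$y[df$w == cmb[1, k]][order(df$s[df$w == cmb[1, k]])]
    b <- df$y[df$w == cmb[2, k]][order(df$s[df$w == cmb[2, k]])]
    tt <- paired_t(a, b)
    tibble(level_a = cmb[1, k], level_b = cmb[2, k], t = tt$t, df = tt$df,
           p_bonferroni = min(1, tt$p * m))
  }))
  structure(list(F = unname(Fv), df1 = df1, df2 = df2, p = unname(p),
                 posthoc = posthoc),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("<rm_anova> F(%d, %d) = %.2f, p = %.3g\n", x$df1, x$df2, x$F,
              x$p))
  print(x$posthoc)
  invisible(x)
}
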