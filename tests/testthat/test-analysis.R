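# ---- independent brute-force oracles for the pairing rules ----

# Naive exhaustive implementation of the paired-trial rules: for every
# triggered stimulation, scan all events for the one containing the
# detection; scan all earlier non-stimulated events for the latest one whose
# duration exceeds the delay.
bf_pair_trials <- function(events, stim_log) {
  events <- events[order(events$onset_s), ]
  contains <- function(d) {
    for (i in seq_len(nrow(events))) {
      if (events$onset_s[i] - 0.1 <= d && d <= events$offset_s[i]) return(i)
    }
    NA_integer_
  }
  trig <- stim_log[stim_log$triggered, ]
  stim_rows <- unique(stats::na.omit(
    vapply(trig$detection_time_s, contains, integer(1))))
  out <- NULL
  for (k in seq_len(nrow(trig))) {
    i <- contains(trig$detection_time_s[k])
    if (is.na(i)) next
    delay <- trig$delay_s[k]
    if (is.na(delay)) delay <- 0
    best <- NA_integer_
    for (j in seq_len(nrow(events))) {
      if (events$onset_s[j] >= events$onset_s[i]) next
      if (j %in% stim_rows) next
      if (events$duration_s[j] <= delay) next
      if (is.na(best) || events$onset_s[j] > events$onset_s[best]) best <- j
    }
    if (is.na(best)) next
    out <- rbind(out, data.frame(
      stim_id = trig$stim_id[k], stim_event = events$event_id[i],
      control_event = events$event_id[best],
      normalized = 100 * events$duration_s[i] / events$duration_s[best]
    ))
  }
  out
}

# Naive implementation of the reshuffle control rule for a fixed selection.
bf_reshuffle_controls <- function(events, selected, qualify_min = 3) {
  events <- events[order(events$onset_s), ]
  out <- NULL
  for (i in selected) {
    if (i < 2) next
    j <- i - 1
    if (events$duration_s[j] < qualify_min) {
      j <- NA_integer_
      for (k in seq_len(i - 1)) {
        if (events$duration_s[k] >= qualify_min) {
          if (is.na(j) || k > j) j <- k
        }
      }
      if (is.na(j)) next
    }
    out <- rbind(out, data.frame(stim_event = events$event_id[i],
                                 control_event = events$event_id[j]))
  }
  out
}

random_stim_log <- function(events, seed) {
  withr::with_seed(seed, {
    n_stim <- max(1, rbinom(1, nrow(events), 0.3))
    idx <- sort(sample(nrow(events), n_stim))
    cls <- sample(c("0", "0.5", "2", ">2"), n_stim, replace = TRUE)
    del <- vapply(cls, function(cl) switch(cl, "0" = 0, "0.5" = 0.5,
                                           "2" = 2, ">2" = runif(1, 2.5, 4.8)),
                  numeric(1))
    tibble::tibble(
      stim_id = seq_len(n_stim),
      detection_time_s = events$onset_s[idx] + 0.01,
      delay_s = del, delay_class = cls,
      light_on_s = events$onset_s[idx] + del, light_duration_s = 10,
      triggered = TRUE, condition = "PV_ChR2"
    )
  })
}

test_that("pair_trials equals the brute-force oracle on random event streams", {
  for (seed in 1:25) {
    ev <- random_event_stream(n = sample(5:20, 1), seed = seed)
    stim <- random_stim_log(ev, seed = 1000 + seed)
    got <- pair_trials(ev, stim)
    want <- bf_pair_trials(ev, stim)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got$stim_event_id, want$stim_event)
      expect_equal(got$control_event_id, want$control_event)
      expect_equal(got$normalized_pct, want$normalized)
    }
  }
})

test_that("pairing follows the stated examples", {
  mk_events <- function(durs, gap = 10) {
    onset <- cumsum(c(0, head(durs, -1))) + gap * (seq_along(durs) - 1)
    tibble::tibble(event_id = seq_along(durs), onset_s = onset,
                   offset_s = onset + durs, duration_s = durs,
                   animal_id = "a")
  }
  stim_at <- function(ev, i, delay = 0, cls = "0") tibble::tibble(
    stim_id = 1L, detection_time_s = ev$onset_s[i] + 0.01, delay_s = delay,
    delay_class = cls, light_on_s = ev$onset_s[i] + delay,
    light_duration_s = 10, triggered = TRUE, condition = "PV_ChR2"
  )
  # immediate control: [..., 4.0 s, (stim) 2.6 s] -> normalized 65%
  ev <- mk_events(c(3, 4, 2.6))
  p <- pair_trials(ev, stim_at(ev, 3))
  expect_equal(p$control_event_id, 2)
  expect_equal(p$normalized_pct, 65)
  # control substitution: delay 3.5 s skips the 2.0-s event
  ev2 <- mk_events(c(5, 2, 6))
  p2 <- pair_trials(ev2, stim_at(ev2, 3, delay = 3.5, cls = ">2"))
  expect_equal(p2$control_event_id, 1)
  expect_equal(p2$control_duration_s, 5)
  # no prior event: trial dropped with a logged reason
  ev3 <- mk_events(c(4))
  p3 <- pair_trials(ev3, stim_at(ev3, 1))
  expect_equal(nrow(p3), 0)
  expect_equal(nrow(attr(p3, "dropped")), 1)
  # trials failing the pre-stimulation gate are dropped
  s <- stim_at(ev, 3)
  s$gate_pass <- FALSE
  pg <- pair_trials(ev, s)
  expect_equal(nrow(pg), 0)
  expect_match(attr(pg, "dropped")$reason, "gate")
})

test_that("normalized duration is the stated percentage", {
  expect_equal(normalized_duration(2, 2), 100)
  expect_equal(normalized_duration(5.404, 4), 135.1)
  expect_equal(normalized_duration(1.31, 4), 32.75)
  expect_error(normalized_duration(1, 0), "> 0")
})

test_that("offline segmentation matches ground truth and its gap/duration rules", {
  ses <- fixture_session()
  rec <- minmax_scale(ses$recording)
  ev <- segment_events(rec)
  gt <- seizure_events(ses$recording)
  err <- vapply(seq_len(nrow(gt)), function(i) {
    j <- which(abs(ev$onset_s - gt$onset_s[i]) < 0.3)
    if (length(j)) abs(ev$duration_s[j[1]] - gt$duration_s[i]) else Inf
  }, numeric(1))
  expect_gte(mean(err <= 0.2), 0.95)
  # State-1 bursts (<= 150 ms) never reach the minimum duration
  s1 <- fixture_state_recording("S1_INTERICTAL", duration = 120, seed = 31)
  expect_equal(nrow(segment_events(minmax_scale(s1), min_duration = 0.5)), 0)
  # two discharges 0.1 s apart merge under the 0.3-s gap rule
  fs <- 512
  x <- withr::with_seed(4, ictalloop:::pink_noise(30 * fs, 25))
  w1 <- generate_seizure_waveform(2, seed = 5)
  w2 <- generate_seizure_waveform(2, seed = 6)
  x[(10 * fs):(10 * fs + length(w1) - 1)] <- x[(10 * fs):(10 * fs + length(w1) - 1)] + w1
  at2 <- round(12.1 * fs)
  x[at2:(at2 + length(w2) - 1)] <- x[at2:(at2 + length(w2) - 1)] + w2
  merged <- segment_events(minmax_scale(ecog_recording(x)), min_gap = 0.3)
  expect_equal(nrow(merged), 1)
  expect_gt(merged$duration_s, 3.5)
})

test_that("window analysis assigns events by onset and aggregates per animal", {
  ev <- tibble::tibble(
    event_id = 1:5, onset_s = c(89, 95, 102, 104, 112),
    offset_s = c(94, 97, 105, 105, 116),
    duration_s = c(5, 2, 3, 1, 4), animal_id = "a"
  )
  stim <- tibble::tibble(stim_id = 1L, detection_time_s = 100, delay_s = 0,
                         delay_class = "continuous", light_on_s = 100,
                         light_duration_s = 10, triggered = TRUE,
                         condition = "PV_ChR2")
  w <- window_analysis(ev, stim)
  s <- w$summary
  expect_equal(s$mean_duration_s[s$window == "pre"], 2)
  expect_equal(s$mean_duration_s[s$window == "during"], 2)
  expect_equal(s$mean_duration_s[s$window == "post"], 4)
  # no events at all: zero counts
  w0 <- window_analysis(ev[0, ], stim)
  expect_true(all(w0$per_animal$n_events == 0))
})

test_that("reshuffle follows eligibility and qualifying-control rules", {
  # identical durations: every pseudo-trial normalizes to exactly 100%
  ev <- tibble::tibble(event_id = 1:12, onset_s = seq(0, 110, by = 10),
                       offset_s = seq(0, 110, by = 10) + 4,
                       duration_s = rep(4, 12), animal_id = "a")
  r <- reshuffle_null(ev, seed = 1)
  expect_gt(nrow(r), 0)
  expect_true(all(r$normalized_pct == 100))
  # [..., 2.0, 3.5, (pseudo) 4.0]: the 2.0-s event is skipped (< 3 s)
  ev2 <- tibble::tibble(event_id = 1:3, onset_s = c(0, 10, 20),
                        offset_s = c(2, 13.5, 24),
                        duration_s = c(2, 3.5, 4), animal_id = "a")
  r2 <- reshuffle_null(ev2, seed = 1, p_select = 1)
  last <- r2[r2$stim_event_id == 3, ]
  expect_equal(last$control_duration_s, 3.5)
  # matches the brute-force control rule when everything eligible is selected
  for (seed in 1:15) {
    evr <- random_event_stream(n = sample(6:20, 1), seed = 300 + seed)
    got <- reshuffle_null(evr, seed = 1, p_select = 1)
    sel <- which(evr$duration_s > 2.5)
    want <- bf_reshuffle_controls(evr, sel)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got$stim_event_id, want$stim_event)
      expect_equal(got$control_event_id, want$control_event)
    }
  }
})

test_that("per-animal aggregation weights animals, not trials", {
  pairs <- tibble::tibble(
    stim_id = 1:6, animal_id = c("a", "a", "b", "b", "b", "b"),
    condition = "X", delay_class = "0", delay_s = 0,
    stim_event_id = 1:6, control_event_id = 1:6,
    stim_duration_s = c(0.9, 1.1, 2, 2, 2, 2) * 2,
    control_duration_s = 2,
    normalized_pct = c(90, 110, 200, 200, 200, 200)
  )
  agg <- per_animal_aggregate(pairs)
  expect_equal(agg$mean_normalized_pct[agg$animal_id == "a"], 100)
  g <- group_normalized_duration(pairs)
  expect_equal(g$mean_pct, 150)   # (100 + 200) / 2, not the trial mean
  # duplicating every trial of one animal leaves the group mean unchanged
  dup <- dplyr::bind_rows(pairs, pairs[pairs$animal_id == "b", ])
  expect_equal(group_normalized_duration(dup)$mean_pct, g$mean_pct)
})

test_that("paired t-test matches the textbook formula and flags degeneracy", {
  a <- c(5.1, 4.8, 6.0, 5.5, 4.9)
  b <- c(4.0, 4.4, 5.1, 4.2, 4.6)
  d <- a - b
  want_t <- mean(d) / (sd(d) / sqrt(length(d)))
  got <- paired_t(a, b)
  expect_equal(got$t, want_t)
  expect_equal(got$df, 4)
  expect_equal(got$p, 2 * stats::pt(-abs(want_t), 4))
  same <- paired_t(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  degen <- paired_t(a + 1, a)
  expect_true(degen$degenerate)
  expect_error(paired_t(a, b[-1]), "equal length")
  expect_error(paired_t(1, 2), "at least 2")
})

test_that("repeated-measures ANOVA reproduces a hand-computed SS table", {
  # 3 animals x 3 windows; sums of squares computed by hand:
  # grand mean 4; window means 3, 13/3, 14/3; subject means 3, 4, 5
  # SS_window  = 3 * (1 + 1/9 + 4/9) = 14/3, df 2
  # SS_subject = 3 * (1 + 0 + 1) = 6
  # SS_total   = 12 -> SS_resid = 12 - 14/3 - 6 = 4/3, df 4
  # F = (14/6) / (4/12) = 7
  df <- data.frame(
    animal_id = rep(c("a", "b", "c"), each = 3),
    window = rep(c("pre", "during", "post"), 3),
    mean_duration_s = c(2, 3, 4, 3, 4, 5, 4, 6, 5)
  )
  fit <- rm_anova_bonferroni(df)
  expect_equal(fit$df1, 2)
  expect_equal(fit$df2, 4)
  expect_equal(fit$F, 7)
  expect_equal(nrow(fit$posthoc), 3)
  expect_true(all(fit$posthoc$p_bonferroni <= 1))
})

test_that("repeated-measures ANOVA reports F(2, 12) for 7 animals", {
  df <- withr::with_seed(9, data.frame(
    animal_id = rep(letters[1:7], each = 3),
    window = rep(c("pre", "during", "post"), 7),
    mean_duration_s = rnorm(21, rep(c(3, 2, 3), 7), 0.3)
  ))
  fit <- rm_anova_bonferroni(df)
  expect_equal(c(fit$df1, fit$df2), c(2, 12))
  # identical windows: no effect, post hoc p = 1
  flat <- df
  flat$mean_duration_s <- rep(1:7, each = 3)
  f0 <- rm_anova_bonferroni(flat)
  expect_equal(f0$F, 0)
  expect_equal(f0$p, 1)
  expect_true(all(f0$posthoc$p_bonferroni == 1))
  # incomplete designs are rejected
  expect_error(rm_anova_bonferroni(df[-1, ]), "Incomplete")
})
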