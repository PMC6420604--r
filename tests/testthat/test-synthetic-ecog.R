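test_that("degenerate durations yield a minimal recording with no events", {
  rec <- generate_recording(condition_profile("NO_OPSIN"), 0.02, seed = 1)
  expect_gte(length(rec$samples), 1)
  expect_equal(nrow(seizure_events(rec)), 0)
  expect_error(generate_recording(condition_profile("NO_OPSIN"), -1, 1),
               "positive")
})

test_that("equal seeds give bit-identical recordings and ground truth", {
  prof <- condition_profile("PV_ChR2")
  pol <- scheduler_policy()
  a <- generate_recording(prof, 120, seed = 9, policy = pol)
  b <- generate_recording(prof, 120, seed = 9, policy = pol)
  expect_identical(a$samples, b$samples)
  expect_identical(seizure_events(a), seizure_events(b))
  expect_identical(stim_events(a), stim_events(b))
  c <- generate_recording(prof, 120, seed = 10, policy = pol)
  expect_false(identical(a$samples, c$samples))
})

test_that("state intervals tile the recording exactly", {
  for (s in c(1, 2, 3)) {
    rec <- generate_recording(condition_profile("NO_OPSIN"), 200, seed = s)
    iv <- state_intervals(rec)
    expect_equal(sum(iv$end_s - iv$start_s), rec$duration)
    expect_true(all(diff(iv$start_s) > 0))
    expect_true(all(iv$end_s[-nrow(iv)] == iv$start_s[-1]))
  }
})

test_that("every seizure event lies inside a State-2 interval", {
  rec <- generate_recording(condition_profile("NO_OPSIN"), 400, seed = 4)
  iv <- state_intervals(rec)
  s2 <- iv[iv$state == "S2_ICTAL", ]
  ev <- seizure_events(rec)
  inside <- vapply(seq_len(nrow(ev)), function(i) {
    any(s2$start_s <= ev$onset_s[i] + 1e-9 &
          ev$offset_s[i] <= s2$end_s + 1e-9)
  }, logical(1))
  expect_true(all(inside))
})

test_that("event onset rate matches the configured seizure rate", {
  rec <- fixture_s2_recording(duration = 600, seed = 1)
  ev <- seizure_events(rec)
  rate <- nrow(ev) / rec$duration
  expect_gt(rate, 0.16)
  expect_lt(rate, 0.24)
})

test_that("empirical mean duration approaches the configured lognormal mean", {
  rec <- fixture_s2_recording(duration = 3600, seed = 7)
  ev <- seizure_events(rec)
  free <- ev[ev$role == "free", ]
  target <- condition_profile("NO_OPSIN")$control_duration_mean_by_delay[["0"]]
  expect_lt(abs(mean(free$duration_s) - target) / target, 0.05)
})

test_that("seizure waveform: sentinel is the arg-min and leads the event", {
  fs <- 512
  w <- generate_seizure_waveform(3, seed = 0)
  expect_lte(which.min(w), round(0.1 * fs))
  # sentinel-only event when duration equals the sentinel width
  p <- seizure_waveform_params()
  w2 <- generate_seizure_waveform(p$sentinel_width_s, seed = 0)
  expect_equal(length(w2), round(p$sentinel_width_s * fs))
  expect_lt(min(w2), 0.9 * p$sentinel_amplitude * 0.95)
})

test_that("seizure body carries high-frequency power that baseline lacks", {
  fs <- 512
  w <- generate_seizure_waveform(10, seed = 3)
  base <- withr::with_seed(3, ictalloop:::pink_noise(length(w), 25))
  band_ratio <- function(x) {
    sp <- stats::spec.pgram(stats::ts(x, frequency = fs), plot = FALSE,
                            spans = 9)
    hf <- sp$freq >= 60 & sp$freq <= 120
    lf <- sp$freq < 5
    sum(sp$spec[hf]) / sum(sp$spec[lf])
  }
  expect_gt(band_ratio(w), band_ratio(base))
})

test_that("interictal bursts stay within 100-150 ms", {
  p <- seizure_waveform_params()
  expect_identical(p$burst_len_range, c(0.100, 0.150))
  for (len in runif(10, p$burst_len_range[1], p$burst_len_range[2])) {
    b <- ictalloop:::burst_waveform(len, p, 512)
    expect_lte(length(b) / 512, 0.151)
    expect_gte(length(b) / 512, 0.099)
  }
})

test_that("stimulation effect is the deterministic programmed multiplier", {
  pv <- condition_profile("PV_ChR2")
  expect_equal(apply_stimulation_effect(4, "0", pv), 2.62)
  expect_equal(apply_stimulation_effect(4, ">2", pv), 5.404)
  no <- condition_profile("NO_OPSIN")
  for (cl in c("0", "0.5", "2", ">2", "continuous")) {
    expect_equal(apply_stimulation_effect(4, cl, no), 4)
  }
  expect_error(apply_stimulation_effect(4, "7s", pv), "delay class")
  expect_error(apply_stimulation_effect(-1, "0", pv), "positive")
})

test_that("control-duration draws match the configured per-class means", {
  prof <- condition_profile("PV_ChR2")
  withr::with_seed(1, {
    d0 <- draw_control_duration("0", prof, n = 20000)
    d05 <- draw_control_duration("0.5", prof, n = 20000)
    dl <- draw_control_duration(">2", prof, n = 2000, delay = 3.5)
  })
  expect_lt(abs(mean(d0) - 3.31) / 3.31, 0.03)
  expect_lt(abs(mean(d05) - 3.66) / 3.66, 0.03)
  expect_true(all(dl > 3.5))   # truncated below the realized delay
})

test_that("profile table is validated", {
  expect_error(condition_profile("NOT_A_THING"), "Unknown condition")
  expect_error(condition_profile("PV_ChR2",
    duration_multiplier_by_delay = c("0" = -1)), "positive")
  no <- condition_profile("NO_OPSIN")
  expect_true(all(no$duration_multiplier_by_delay == 1))
})

test_that("ground truth marks realized and counterfactual durations", {
  ses <- fixture_session()
  ev <- seizure_events(ses$recording)
  st <- ev[ev$role == "stim", ]
  expect_gt(nrow(st), 5)
  expect_equal(st$duration_s / st$counterfactual_s,
               rep(0.655, nrow(st)), tolerance = 1e-10)
  no <- run_closed_loop_session(condition_profile("NO_OPSIN"),
                                scheduler_policy(), 300, seed = 2)
  evn <- seizure_events(no$recording)
  stn <- evn[evn$role == "stim", ]
  expect_equal(stn$duration_s, stn$counterfactual_s)
})
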