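# Shared fixtures, built once per test run and cached. Everything is
# generated in code; nothing is read from disk.

.fx <- new.env(parent = emptyenv())

# Small labeled feature set (4 train + 2 test animals, 5 epochs/state) and a
# classifier trained on it.
fixture_features <- function() {
  if (is.null(.fx$features)) {
    .fx$features <- training_epoch_features(
      n_train_animals = 4, n_test_animals = 2, epochs_per_state = 5, seed = 77
    )
  }
  .fx$features
}

fixture_model <- function() {
  if (is.null(.fx$model)) {
    .fx$model <- train_state_classifier(fixture_features()$train, seed = 77)
  }
  .fx$model
}

# One 600-s PV_ChR2 closed-loop session, immediate (0 s) stimulation.
fixture_session <- function() {
  if (is.null(.fx$session)) {
    .fx$session <- run_closed_loop_session(
      condition_profile("PV_ChR2"),
      scheduler_policy(delay_weights = c("0" = 1)),
      duration = 600, seed = 3, animal_id = "m1"
    )
  }
  .fx$session
}

# A pure State-2 NO_OPSIN stream (for detector / reshuffle material).
fixture_s2_recording <- function(duration = 600, seed = 101) {
  generate_recording(
    condition_profile("NO_OPSIN"), duration, seed, animal_id = "s2",
    state_mix = c(BASELINE = 0, S1_INTERICTAL = 0, S2_ICTAL = 1,
                  S3_CONTINUOUS = 0)
  )
}

# A single-state recording of the given network state.
fixture_state_recording <- function(state, duration = 65, seed = 5) {
  mix <- setNames(as.numeric(state_levels() == state), state_levels())
  generate_recording(condition_profile("NO_OPSIN"), duration, seed,
                     animal_id = "fx", state_mix = mix)
}

# Random synthetic event tables for pairing-rule property tests (pure
# tables, no signal involved).
random_event_stream <- function(n, seed) {
  withr::with_seed(seed, {
    dur <- exp(rnorm(n, log(3), 0.6))
    gap <- runif(n, 0.5, 25)
    onset <- cumsum(gap + dplyr::lag(dur, default = 0))
    tibble::tibble(
      event_id = seq_len(n), onset_s = onset, offset_s = onset + dur,
      duration_s = dur, animal_id = "sim"
    )
  })
}
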