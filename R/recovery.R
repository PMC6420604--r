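#' Parameter-recovery runs of the full pipeline
#'
#' These helpers run the complete analysis chain on freshly simulated data
#' and measure how well it recovers the programmed condition effects — the
#' package's main validation device, since no raw in vivo recordings are
#' publicly deposited. Each returns quantities computed entirely by the
#' pipeline (simulation, detection, segmentation, gating, pairing,
#' per-animal aggregation).
#'
#' @name recovery
NULL

#' @describeIn recovery Train on labeled epochs from `n_train` simulated
#'   animals and compute the macro F1 on held-out epochs from `n_test`
#'   unseen animals.
#' @param seed Master seed.
#' @param n_train,n_test Numbers of simulated training / test animals.
#' @param epochs_per_state Epochs per state per animal (25 gives ~700
#'   training epochs from 7 animals).
#' @param test_epochs_per_state Epochs per state per held-out animal (17
#'   gives ~200 test epochs from 3 animals).
#' @return `recover_classifier_f1`: list with `macro_f1`, `n_train_epochs`,
#'   `n_test_epochs`, `model`, `eval`.
#' @export
recover_classifier_f1 <- function(seed = 1, n_train = 7, n_test = 3,
                                  epochs_per_state = 25,
                                  test_epochs_per_state = epochs_per_state) {
  fe <- training_epoch_features(n_train, n_test, epochs_per_state, seed,
                                test_epochs_per_state = test_epochs_per_state)
  fit <- train_state_classifier(fe$train, seed = seed)
  ev <- evaluate_state_classifier(fit, fe$test)
  list(macro_f1 = ev$macro_f1, n_train_epochs = nrow(fe$train),
       n_test_epochs = ev$n, model = fit, eval = ev)
}

#' @describeIn recovery Simulate a closed-loop cohort under one condition
#'   with all stimulated trials in one delay class, run detection,
#'   segmentation, optional classifier gating and the paired analysis, and
#'   return the group normalized-duration result.
#' @param condition Condition name (see [condition_profile()]).
#' @param delay_class `"0"`, `"0.5"`, `"2"` or `">2"`.
#' @param n_animals Cohort size.
#' @param duration_s Session length per animal, seconds.
#' @param model Optional `state_classifier` used to gate trials on their
#'   pre-stimulation epoch.
#' @return `recover_condition_effect`: a `group_result`
#'   (see [group_normalized_duration()]).
#' @export
recover_condition_effect <- function(condition, delay_class, n_animals,
                                     duration_s = 900, seed = 1,
                                     model = NULL) {
  prof <- condition_profile(condition)
  pol <- scheduler_policy(delay_weights = setNames(1, delay_class))
  coh <- simulate_cohort(prof, n_animals, pol, duration_s, seed)
  pairs <- bind_rows(lapply(coh, function(s) {
    rec <- minmax_scale(s$recording)
    ev <- segment_events(rec)
    stim <- s$stim_log
    if (!is.null(model)) stim <- gate_pre_stimulation(model, rec, stim)
    pair_trials(ev, stim)
  }))
  group_normalized_duration(pairs)
}

#' @describeIn recovery Generate unstimulated (NO_OPSIN) State-2 event
#'   streams, segment them and apply the reshuffled pseudo-stimulation
#'   procedure.
#' @return `recover_reshuffle_null`: a `group_result`.
#' @export
recover_reshuffle_null <- function(n_animals = 5, duration_s = 600,
                                   seed = 1) {
  prof <- condition_profile("NO_OPSIN")
  pairs <- bind_rows(lapply(seq_len(n_animals), function(i) {
    rec <- generate_recording(
      prof, duration_s, seed = derive_seed(seed, i),
      animal_id = sprintf("m%02d", i),
      state_mix = c(BASELINE = 0, S1_INTERICTAL = 0, S2_ICTAL = 1,
                    S3_CONTINUOUS = 0)
    )
    ev <- segment_events(minmax_scale(rec))
    reshuffle_null(ev, seed = derive_seed(seed, 1000 + i))
  }))
  group_normalized_duration(pairs)
}

#' @describeIn recovery Continuous-stimulation window analysis with the
#'   pre-light mean calibrated to a target value: a small unstimulated pilot
#'   cohort measures the mapping from the configured duration mean to the
#'   observed pre-window mean (onset-in-window sampling under-weights slow
#'   high-duration stretches, so the observed mean sits below the marginal
#'   mean), the condition's duration scale is adjusted accordingly, and the
#'   stimulated cohort is then analysed.
#' @param target_pre_s Calibration target for the pre-light mean duration.
#' @return `recover_window_effect`: list with the calibrated `summary`
#'   tibble (pre/during/post group means +- s.e.m.), `per_animal`, and the
#'   calibration factor.
#' @export
recover_window_effect <- function(n_animals = 7, duration_s = 600, seed = 1,
                                  target_pre_s = 2.84) {
  pol <- scheduler_policy(mode = "continuous")
  run <- function(profile, n, sd) {
    coh <- simulate_cohort(profile, n, pol, duration_s, sd)
    bind_rows(lapply(coh, function(s) {
      ev <- segment_events(minmax_scale(s$recording))
      window_analysis(ev, s$stim_log)$per_animal
    }))
  }
  # pilot: no stimulation effect, measure the observed pre-window mean
  pilot_prof <- condition_profile("NO_OPSIN")
  pilot <- run(pilot_prof, max(3, n_animals %/% 2), derive_seed(seed, 77))
  pre_obs <- mean(pilot$mean_duration_s[pilot$window == "pre"], na.rm = TRUE)
  factor <- target_pre_s / pre_obs
  prof <- condition_profile("PV_ChR2")
  prof$control_duration_mean_by_delay <-
    prof$control_duration_mean_by_delay * factor
  pa <- run(prof, n_animals, seed)
  summary <- pa %>%
    group_by(.data$window) %>%
    summarise(
      mean_duration_s = mean(.data$mean_duration_s, na.rm = TRUE),
      sem_duration_s = sd(.data$mean_duration_s, na.rm = TRUE) / sqrt(n()),
      mean_rate_hz = mean(.data$rate_hz), .groups = "drop"
    ) %>%
    mutate(window = factor(.data$window, c("pre", "during", "post"))) %>%
    arrange(.data$window)
  list(summary = summary, per_animal = pa, calibration_factor = factor)
}
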