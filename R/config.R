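#' Pipeline configuration
#'
#' Flat key-value configuration tying the pipeline stages together. Defaults
#' reproduce the package's standard analysis settings; the file format is
#' plain-text YAML with an embedded schema version and round-trips
#' losslessly through [write_config()] / [read_config()].
#'
#' @param ... Overrides of any default key.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    schema_version = 1,
    sampling_rate = 512,
    condition = "NO_OPSIN",
    duration_s = 900,
    seed = 1,
    # features
    epoch_s = 10,
    prominence = 0.05,
    baseline_band = 0.02,
    # detector
    detector_k_mad = 6,
    refractory_s = 5,
    # scheduler
    min_interval_s = 20,
    light_duration_s = 10,
    delay_weights = c("0" = 1, "0.5" = 1, "2" = 1, ">2" = 1),
    # offline analysis
    segment_k_mad = 4,
    min_gap_s = 0.3,
    min_duration_s = 0.5,
    reshuffle_eligible_min_s = 2.5,
    reshuffle_qualify_min_s = 3,
    # classifier
    num_trees = 200
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    abort(paste("Unknown config keys:", paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path File path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- unclass(config)
  # yaml drops names of atomic vectors; store weights as a map
  out$delay_weights <- as.list(out$delay_weights)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$schema_version)) abort("Config lacks a schema_version.")
  if (!is.null(raw$delay_weights)) {
    raw$delay_weights <- unlist(raw$delay_weights)
  }
  do.call(pipeline_config, raw[setdiff(names(raw), "schema_version")])
}

#' Run one pipeline command
#'
#' File-to-file driver used by the `ictal-loop` command line: each command
#' reads and writes only the documented EDF/CSV/model artifacts and logs the
#' seeds it consumed. Commands: `simulate` (session EDF + stimulation log +
#' ground truth), `train` (classifier artifact from a synthetic labeled
#' cohort), `classify` (per-epoch state labels), `detect` (online detection
#' times), `analyze` (events, trial pairs and a group report), `reshuffle`
#' (pseudo-stimulation null report), `report` (group summary from a pairs
#' file).
#'
#' @param config A [pipeline_config()].
#' @param command One of the commands above.
#' @param edf,log,model,pairs Input paths (as each command requires).
#' @param out Output directory (created if missing).
#' @return Invisibly, a named list of written artifact paths.
#' @export
run_pipeline <- function(config, command = c("simulate", "train", "classify",
                                             "detect", "analyze", "reshuffle",
                                             "report"),
                         edf = NULL, log = NULL, model = NULL, pairs = NULL,
                         out = ".") {
  command <- match.arg(command)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  message(sprintf("[ictal-loop] %s | condition=%s seed=%d",
                  command, config$condition, config$seed))
  p <- function(...) file.path(out, paste0(...))
  need <- function(path, what) {
    if (is.null(path) || !file.exists(path)) {
      abort(sprintf("Command '%s' needs an existing %s file.", command, what))
    }
    path
  }
  written <- list()

  if (command == "simulate") {
    prof <- condition_profile(config$condition)
    pol <- scheduler_policy(min_interval = config$min_interval_s,
                            delay_weights = config$delay_weights,
                            light_duration = config$light_duration_s)
    ses <- run_closed_loop_session(prof, pol, config$duration_s, config$seed)
    written$edf <- write_ecog(ses$recording, p("session.edf"))
    written$stim_log <- write_stim_log(ses$stim_log, p("stim.csv"))
    written$ground_truth <- write_ground_truth(ses$recording, p("truth.csv"))
  } else if (command == "train") {
    feats <- training_epoch_features(n_train_animals = 7, n_test_animals = 0,
                                     epochs_per_state = 7, seed = config$seed)
    fit <- train_state_classifier(feats$train, seed = config$seed,
                                  num_trees = config$num_trees)
    written$model <- save_state_classifier(fit, p("model.rds"))
  } else if (command == "classify") {
    rec <- read_ecog(need(edf, "EDF"))
    fit <- load_state_classifier(need(model, "model"))
    feats <- epoch_features(rec, config$epoch_s, config$prominence,
                            config$baseline_band)
    cls <- classify_epochs(fit, feats)
    written$labels <- write_table_csv(cls, p("epoch_labels.csv"))
  } else if (command == "detect") {
    rec <- minmax_scale(read_ecog(need(edf, "EDF")))
    thr <- auto_threshold(rec, k = config$detector_k_mad)
    det <- detect_onsets(rec, thr, config$refractory_s)
    written$detections <- write_table_csv(det, p("detections.csv"))
  } else if (command == "analyze") {
    rec <- minmax_scale(read_ecog(need(edf, "EDF")))
    stim <- read_stim_log(need(log, "stimulation log"))
    ev <- segment_events(rec, k_mad = config$segment_k_mad,
                         min_gap = config$min_gap_s,
                         min_duration = config$min_duration_s)
    if (!is.null(model)) {
      fit <- load_state_classifier(model)
      stim <- gate_pre_stimulation(fit, rec, stim)
    }
    pr <- pair_trials(ev, stim)
    written$events <- write_table_csv(ev, p("events.csv"))
    written$pairs <- write_table_csv(pr, p("pairs.csv"))
    if (nrow(pr)) {
      res <- group_normalized_duration(pr)
      written$report <- write_table_csv(glance(res), p("report.csv"))
    }
  } else if (command == "reshuffle") {
    rec <- minmax_scale(read_ecog(need(edf, "EDF")))
    ev <- segment_events(rec, k_mad = config$segment_k_mad,
                         min_gap = config$min_gap_s,
                         min_duration = config$min_duration_s)
    pr <- reshuffle_null(ev, seed = config$seed,
                         eligible_min = config$reshuffle_eligible_min_s,
                         qualify_min = config$reshuffle_qualify_min_s)
    written$pairs <- write_table_csv(pr, p("pseudo_pairs.csv"))
    if (nrow(pr)) {
      written$report <- write_table_csv(glance(group_normalized_duration(pr)),
                                        p("reshuffle_report.csv"))
    }
  } else if (command == "report") {
    pr <- read_table_csv(need(pairs, "pairs"))
    written$report <- write_table_csv(glance(group_normalized_duration(pr)),
                                      p("report.csv"))
  }
  invisible(written)
}

#' Labeled epoch features from simulated cohorts
#'
#' Convenience generator of classifier training/testing material: for each
#' simulated animal, one single-state recording per network state is
#' generated, segmented into 10-s epochs and featurised. Test animals are
#' distinct from training animals (ids and seeds), so evaluation is
#' leakage-free by construction.
#'
#' @param n_train_animals,n_test_animals Cohort sizes.
#' @param epochs_per_state Epochs per state per training animal.
#' @param seed Master seed.
#' @param profile A [condition_profile()] (only its background event
#'   statistics matter here).
#' @param test_epochs_per_state Epochs per state per test animal (defaults
#'   to `epochs_per_state`).
#' @return List with feature tibbles `train` and `test`.
#' @export
training_epoch_features <- function(n_train_animals = 7, n_test_animals = 3,
                                    epochs_per_state = 7, seed = 1,
                                    profile = condition_profile("NO_OPSIN"),
                                    test_epochs_per_state = epochs_per_state) {
  states <- state_levels()
  gen <- function(ids, off, eps) {
    bind_rows(lapply(ids, function(a) {
      bind_rows(lapply(seq_along(states), function(si) {
        st <- states[si]
        mix <- setNames(as.numeric(states == st), states)
        rec <- generate_recording(
          profile, duration = eps * 10 + 5,
          seed = derive_seed(seed, off + a * 10 + si),
          animal_id = sprintf("%s%02d", if (off) "test" else "train", a),
          state_mix = mix
        )
        f <- epoch_features(rec)
        f$label <- st
        f
      }))
    }))
  }
  list(
    train = gen(seq_len(n_train_animals), 0, epochs_per_state),
    test = if (n_test_animals > 0) {
      gen(seq_len(n_test_animals), 5000, test_epochs_per_state)
    } else NULL
  )
}
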