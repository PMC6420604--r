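#' Train the random-forest network-state classifier
#'
#' Fits a probability random forest to labeled 20-feature epochs
#' (see [epoch_features()]). Labels must be generator states (never `MIXED`)
#' and at least two classes must be present. Training is deterministic given
#' `seed` (single-threaded forest).
#'
#' @param features A tibble containing the 20 feature columns, a label column
#'   and (ideally) `animal_id` — used later to assert leakage-free
#'   evaluation.
#' @param label Name of the label column (default `"label"`).
#' @param seed Integer seed recorded in the model metadata.
#' @param num_trees Number of trees (default 200).
#' @param ... Further arguments to [ranger::ranger()] (e.g. `max.depth`).
#' @return A `state_classifier` object.
#' @export
train_state_classifier <- function(features, label = "label", seed = 1,
                                   num_trees = 200, ...) {
  if (!label %in% names(features)) abort(sprintf("No '%s' column.", label))
  labs <- as.character(features[[label]])
  keep <- !is.na(labs)
  features <- features[keep, , drop = FALSE]
  labs <- labs[keep]
  if (any(labs == mixed_label())) {
    abort("MIXED is a classifier output, not a training label.")
  }
  if (length(unique(labs)) < 2) {
    abort("Training data must contain at least two classes.")
  }
  fm <- as.matrix(features[, feature_names(), drop = FALSE])
  if (anyNA(fm)) abort("Feature matrix contains missing values.")
  dat <- data.frame(fm)
  dat$.state <- factor(labs)
  forest <- ranger::ranger(
    dependent.variable.name = ".state", data = dat,
    probability = TRUE, num.trees = num_trees, seed = seed,
    num.threads = 1, importance = "impurity", ...
  )
  structure(
    list(
      forest = forest,
      classes = levels(dat$.state),
      feature_names = feature_names(),
      training_animals = unique(as.character(features$animal_id %||% character())),
      meta = list(n_epochs = nrow(features), seed = seed,
                  num_trees = num_trees)
    ),
    class = "state_classifier"
  )
}

#' @export
print.state_classifier <- function(x, ...) {
  cat(sprintf(
    "<state_classifier> %d-class random forest (%d trees, %d epochs, seed %d)\n",
    length(x$classes), x$meta$num_trees, x$meta$n_epochs, x$meta$seed
  ))
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  invisible(x)
}

#' The 2x confidence rule
#'
#' An epoch is assigned its most likely state only when that state's
#' probability is at least twice the second most likely state's; otherwise it
#' is deemed `MIXED`. The boundary (exactly twice) counts as confident, since
#' only "less than twice" is mixed. The rule is scale-free: multiplying all
#' probabilities by a constant cannot change the outcome.
#'
#' @param probs Numeric matrix (rows = epochs) or vector of class
#'   probabilities, with class names as (column) names.
#' @return A tibble with `label`, `confident`, `top_prob`, `second_prob`.
#' @export
confidence_rule <- function(probs) {
  if (is.null(dim(probs))) probs <- matrix(probs, 1,
                                           dimnames = list(NULL, names(probs)))
  cls <- colnames(probs)
  ord <- t(apply(probs, 1, order, decreasing = TRUE))
  top <- probs[cbind(seq_len(nrow(probs)), ord[, 1])]
  second <- probs[cbind(seq_len(nrow(probs)), ord[, 2])]
  confident <- top >= 2 * second
  tibble(
    label = ifelse(confident, cls[ord[, 1]], mixed_label()),
    confident = confident,
    top_prob = top,
    second_prob = second
  )
}

#' Classify feature epochs with mixed-state exclusion
#'
#' Predicts state probabilities for each row and applies the 2x
#' [confidence_rule()]; unconfident epochs are labeled `MIXED`.
#'
#' @param model A [train_state_classifier()] fit.
#' @param features Tibble (or matrix) holding exactly the 20 named feature
#'   columns; extra id columns are passed through.
#' @return The id columns of `features` plus per-class probability columns
#'   (`prob_<STATE>`), `label` and `confident`.
#' @export
classify_epochs <- function(model, features) {
  stopifnot(inherits(model, "state_classifier"))
  fcols <- intersect(names(as.data.frame(features)), model$feature_names)
  if (length(fcols) != length(model$feature_names)) {
    abort(sprintf("Expected %d feature columns, found %d.",
                  length(model$feature_names), length(fcols)))
  }
  fm <- as.data.frame(features)[, model$feature_names, drop = FALSE]
  probs <- predict(model$forest, data = fm, num.threads = 1)$predictions
  colnames(probs) <- model$forest$forest$levels %||% colnames(probs)
  probs <- probs[, model$classes, drop = FALSE]
  rule <- confidence_rule(probs)
  ids <- as_tibble(features)[, setdiff(names(features), model$feature_names),
                             drop = FALSE]
  ids <- ids[, setdiff(names(ids), c("label", "confident")), drop = FALSE]
  names(ids) <- if (ncol(ids)) paste0(names(ids)) else character()
  prob_tbl <- as_tibble(probs, .name_repair = "minimal")
  names(prob_tbl) <- paste0("prob_", model$classes)
  bind_cols(ids, prob_tbl, rule)
}

#' Evaluate the classifier on held-out animals
#'
#' Computes per-class precision/recall/F1 on raw (arg-max, ungated)
#' predictions, the macro-averaged F1, and one-vs-rest ROC coordinates per
#' class. Evaluation must be leakage-free: if `features` carries
#' `animal_id`, any overlap with the training animals is an error.
#'
#' @param model A `state_classifier`.
#' @param features Labeled feature tibble from unseen animals.
#' @param label Label column name.
#' @return A `classifier_eval` list: `per_class` tibble, `macro_f1`,
#'   `roc` tibble (`class`, `fpr`, `tpr`), `n`.
#' @export
evaluate_state_classifier <- function(model, features, label = "label") {
  labs <- as.character(features[[label]])
  keep <- !is.na(labs)
  features <- features[keep, , drop = FALSE]
  labs <- labs[keep]
  if (!length(labs)) abort("Empty test set.")
  if ("animal_id" %in% names(features) && length(model$training_animals)) {
    overlap <- intersect(unique(features$animal_id), model$training_animals)
    if (length(overlap)) {
      abort(paste("Test animals overlap training animals:",
                  paste(overlap, collapse = ", ")))
    }
  }
  fm <- as.data.frame(features)[, model$feature_names, drop = FALSE]
  probs <- predict(model$forest, data = fm, num.threads = 1)$predictions
  colnames(probs) <- model$forest$forest$levels %||% colnames(probs)
  probs <- probs[, model$classes, drop = FALSE]
  pred <- model$classes[max.col(probs, ties.method = "first")]
  per_class <- classification_metrics(truth = labs, pred = pred,
                                      classes = model$classes)
  roc <- bind_rows(lapply(model$classes, function(cl) {
    if (!any(labs == cl) || all(labs == cl)) return(NULL)
    r <- pROC::roc(response = labs == cl, predictor = probs[, cl],
                   quiet = TRUE, direction = "<")
    tibble(class = cl, fpr = 1 - r$specificities, tpr = r$sensitivities)
  }))
  structure(
    list(per_class = per_class, macro_f1 = mean(per_class$f1),
         roc = roc, n = length(labs)),
    class = "classifier_eval"
  )
}

# Per-class precision/recall/F1 from labels; absent precision or recall
# counts as 0 (so a never-predicted class contributes F1 = 0).
classification_metrics <- function(truth, pred, classes) {
  bind_rows(lapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    precision <- if (tp + fp > 0) tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (precision + recall > 0) {
      2 * precision * recall / (precision + recall)
    } else 0
    tibble(class = cl, n = sum(truth == cl), precision = precision,
           recall = recall, f1 = f1)
  }))
}

#' @export
print.classifier_eval <- function(x, ...) {
  cat(sprintf("<classifier_eval> %d epochs, macro F1 = %.3f\n", x$n,
              x$macro_f1))
  print(x$per_class)
  invisible(x)
}

#' Project the 20 features to three linear discriminants
#'
#' Standard LDA projection of labeled epochs for visualisation of
#' network-state separation. Constant and duplicated feature columns are
#' dropped before fitting (the projection is unchanged by de-duplication).
#' With `k` classes only `k - 1` discriminants exist; fewer than four classes
#' therefore yield fewer than three dimensions, with a warning.
#'
#' @param features Feature tibble (20 named columns).
#' @param label Label column name.
#' @return Input id columns plus `LD1`..`LD3` (as available) and the label.
#' @export
lda_project <- function(features, label = "label") {
  labs <- as.character(features[[label]])
  keep <- !is.na(labs)
  features <- features[keep, , drop = FALSE]
  labs <- labs[keep]
  fm <- as.matrix(as.data.frame(features)[, feature_names(), drop = FALSE])
  # regularisation: drop constant and duplicated columns, and columns with
  # (near) zero pooled within-class variance, which make the scatter matrix
  # singular
  ok <- apply(fm, 2, sd) > 0
  fm <- fm[, ok, drop = FALSE]
  fm <- fm[, !duplicated(t(fm)), drop = FALSE]
  within_sd <- apply(fm, 2, function(v) {
    sqrt(mean(tapply(v, labs, function(g) mean((g - mean(g))^2))))
  })
  fm <- fm[, within_sd > 1e-3 * apply(fm, 2, sd), drop = FALSE]
  # standardise so that small-magnitude features (wavelet powers) do not
  # trip absolute collinearity tolerances; the projection quality is
  # unaffected by per-feature scaling
  fm <- scale(fm)
  k <- length(unique(labs))
  if (k < 2) abort("LDA needs at least two classes.")
  if (k < 4) warn(sprintf("Only %d classes: returning %d discriminants.",
                          k, k - 1))
  fit <- suppressWarnings(MASS::lda(fm, grouping = factor(labs)))
  proj <- fm %*% fit$scaling
  nd <- min(3, ncol(proj))
  out <- as_tibble(proj[, seq_len(nd), drop = FALSE])
  names(out) <- paste0("LD", seq_len(nd))
  ids <- as_tibble(features)[, intersect(c("animal_id", "epoch_id", "start_s"),
                                         names(features)), drop = FALSE]
  bind_cols(ids, out, tibble(label = labs))
}

#' Gate a stimulation trial on its pre-stimulation epoch
#'
#' Classifies the 10 s of recording immediately preceding each detection and
#' keeps the trial only when that epoch is confidently in State 2 (discrete
#' seizures) under the 2x rule. Trials without a full 10-s pre-epoch are
#' rejected.
#'
#' @param model A `state_classifier`.
#' @param recording The session [ecog_recording()] (scaled or raw).
#' @param stim_log Stimulation log tibble with `detection_time_s` (e.g. from
#'   [run_closed_loop_session()] or [read_stim_log()]).
#' @param epoch_s Pre-epoch length (default 10 s).
#' @return `stim_log` with logical column `gate_pass` plus the classified
#'   pre-epoch label.
#' @export
gate_pre_stimulation <- function(model, recording, stim_log, epoch_s = 10) {
  stopifnot(inherits(model, "state_classifier"))
  if (!recording$scaled) recording <- minmax_scale(recording)
  fs <- recording$sampling_rate
  len <- round(epoch_s * fs)
  plan <- morlet_plan(len, fs)
  res <- lapply(stim_log$detection_time_s, function(d) {
    i1 <- round(d * fs)
    if (is.na(d) || i1 < len) return(tibble(pre_label = NA_character_,
                                            gate_pass = FALSE))
    x <- recording$samples[(i1 - len + 1):i1]
    fv <- extract_features(x, fs, plan = plan)
    cls <- classify_epochs(model, as_tibble(as.list(fv)))
    tibble(pre_label = cls$label,
           gate_pass = cls$label == "S2_ICTAL" & cls$confident)
  })
  bind_cols(stim_log, bind_rows(res))
}

#' @rdname tidy
#' @param x A fitted `state_classifier`.
#' @param ... Unused.
#' @export
tidy.state_classifier <- function(x, ...) {
  imp <- x$forest$variable.importance
  tibble(term = names(imp), importance = unname(imp)) %>%
    arrange(dplyr::desc(.data$importance))
}

#' Broom-style summaries
#'
#' `tidy()` on a `state_classifier` returns per-feature impurity importance;
#' `glance()` returns one-row fit metadata. `tidy()`/`glance()` on a
#' `group_result` return per-animal means and the group-level test.
#'
#' @name tidy
NULL

#' @rdname tidy
#' @export
glance.state_classifier <- function(x, ...) {
  tibble(
    n_epochs = x$meta$n_epochs, num_trees = x$meta$num_trees,
    n_classes = length(x$classes), oob_error = x$forest$prediction.error,
    seed = x$meta$seed
  )
}

#' @rdname tidy
#' @export
glance.classifier_eval <- function(x, ...) {
  tibble(n = x$n, macro_f1 = x$macro_f1)
}

#' @rdname tidy
#' @export
tidy.classifier_eval <- function(x, ...) x$per_class
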