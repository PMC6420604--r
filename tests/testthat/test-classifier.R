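make_toy_features <- function(n_per_class, classes = c("S2_ICTAL", "BASELINE"),
                              sep = 5, seed = 1) {
  withr::with_seed(seed, {
    fm <- matrix(rnorm(n_per_class * length(classes) * 20), ncol = 20,
                 dimnames = list(NULL, feature_names()))
    lab <- rep(classes, each = n_per_class)
    fm[, "std"] <- fm[, "std"] + sep * (as.integer(factor(lab)) - 1)
    out <- tibble::as_tibble(fm)
    out$label <- lab
    out$animal_id <- rep(c("a", "b"), length.out = nrow(out))
    out
  })
}

test_that("training is validated and separable toy data is learned perfectly", {
  toy <- make_toy_features(30)
  fit <- train_state_classifier(toy, seed = 1)
  pred <- classify_epochs(fit, toy)
  expect_equal(pred$label, toy$label)
  one_class <- dplyr::filter(toy, label == "BASELINE")
  expect_error(train_state_classifier(one_class, seed = 1), "two classes")
  mixed <- toy
  mixed$label[1] <- mixed_label()
  expect_error(train_state_classifier(mixed, seed = 1), "MIXED")
})

test_that("training is deterministic given the seed", {
  fe <- fixture_features()
  f1 <- train_state_classifier(fe$train, seed = 123)
  f2 <- train_state_classifier(fe$train, seed = 123)
  p1 <- classify_epochs(f1, fe$test)
  p2 <- classify_epochs(f2, fe$test)
  expect_identical(p1, p2)
})

test_that("the 2x confidence rule handles its boundary and is scale-free", {
  probs <- rbind(
    c(BASELINE = 1, S1_INTERICTAL = 0, S2_ICTAL = 0, S3_CONTINUOUS = 0),
    c(BASELINE = 0.40, S1_INTERICTAL = 0.30, S2_ICTAL = 0.20,
      S3_CONTINUOUS = 0.10),
    c(BASELINE = 0.50, S1_INTERICTAL = 0.25, S2_ICTAL = 0.15,
      S3_CONTINUOUS = 0.10)
  )
  r <- confidence_rule(probs)
  expect_equal(r$confident, c(TRUE, FALSE, TRUE))
  expect_equal(r$label, c("BASELINE", mixed_label(), "BASELINE"))
  # label is MIXED exactly when not confident
  expect_equal(r$label == mixed_label(), !r$confident)
  # multiplying all probabilities by a constant changes nothing
  r10 <- confidence_rule(probs * 13.7)
  expect_equal(r10$confident, r$confident)
  expect_equal(r10$label, r$label)
})

test_that("predicted probability vectors are normalized", {
  fe <- fixture_features()
  pred <- classify_epochs(fixture_model(), fe$test)
  pcols <- grep("^prob_", names(pred))
  expect_true(all(abs(rowSums(pred[, pcols]) - 1) < 1e-9))
  expect_true(all(pred$label %in% c(state_levels(), mixed_label())))
  bad <- fe$test[, -match("std", names(fe$test))]
  expect_error(classify_epochs(fixture_model(), bad), "feature columns")
})

test_that("per-class metrics match a hand-computed confusion matrix", {
  classes <- state_levels()
  truth <- rep(classes, each = 10)
  # perfect predictions
  perfect <- ictalloop:::classification_metrics(truth, truth, classes)
  expect_equal(perfect$f1, rep(1, 4))
  # everything predicted as the first class, balanced truth:
  # predicted class has precision 10/40 = 0.25, recall 1, F1 = 0.4;
  # the three never-predicted classes score 0 -> macro F1 = 0.4 / 4 = 0.1
  allone <- ictalloop:::classification_metrics(
    truth, rep(classes[1], 40), classes
  )
  expect_equal(allone$precision, c(0.25, 0, 0, 0))
  expect_equal(allone$recall, c(1, 0, 0, 0))
  expect_equal(mean(allone$f1), 0.1)
})

test_that("evaluation is leakage-checked and reports ROC coordinates", {
  fe <- fixture_features()
  ev <- evaluate_state_classifier(fixture_model(), fe$test)
  expect_gt(ev$macro_f1, 0.9)
  expect_true(all(c("class", "fpr", "tpr") %in% names(ev$roc)))
  expect_true(all(ev$roc$tpr >= 0 & ev$roc$tpr <= 1))
  expect_error(evaluate_state_classifier(fixture_model(), fe$train),
               "overlap")
  empty <- fe$test[0, ]
  expect_error(evaluate_state_classifier(fixture_model(), empty), "Empty")
})

test_that("LDA projection separates well-separated clusters better than chance", {
  skip_if_not_installed("cluster")
  n <- 40
  feats <- withr::with_seed(5, {
    fm <- matrix(rnorm(4 * n * 20), ncol = 20,
                 dimnames = list(NULL, feature_names()))
    centers <- matrix(rnorm(4 * 20, sd = 4), nrow = 4)
    fm <- fm + centers[rep(1:4, each = n), ]
    out <- tibble::as_tibble(fm)
    out$label <- rep(state_levels(), each = n)
    out
  })
  proj <- lda_project(feats)
  expect_true(all(c("LD1", "LD2", "LD3") %in% names(proj)))
  sil <- function(m) {
    mean(cluster::silhouette(as.integer(factor(feats$label)),
                             dist(m))[, "sil_width"])
  }
  rand <- withr::with_seed(6, {
    q <- qr.Q(qr(matrix(rnorm(20 * 3), 20)))
    as.matrix(feats[, feature_names()]) %*% q
  })
  expect_gt(sil(as.matrix(proj[, c("LD1", "LD2", "LD3")])), sil(rand))
  # permuted labels destroy the separation
  perm <- feats
  perm$label <- withr::with_seed(7, sample(perm$label))
  pproj <- lda_project(perm)
  expect_gt(sil(as.matrix(proj[, c("LD1", "LD2", "LD3")])),
            5 * abs(mean(cluster::silhouette(
              as.integer(factor(perm$label)),
              dist(as.matrix(pproj[, c("LD1", "LD2", "LD3")]))
            )[, "sil_width"])))
})

test_that("LDA tolerates duplicated columns and fewer classes", {
  feats <- make_toy_features(25, classes = c("BASELINE", "S1_INTERICTAL",
                                             "S2_ICTAL"), seed = 8)
  feats$kurtosis <- feats$std       # duplicated feature column
  expect_warning(proj <- lda_project(feats), "2 discriminants")
  expect_true(all(is.finite(as.matrix(proj[, c("LD1", "LD2")]))))
  expect_false("LD3" %in% names(proj))
})

test_that("pre-stimulation gating keeps only confident State-2 epochs", {
  model <- fixture_model()
  s2 <- fixture_s2_recording(duration = 120, seed = 21)
  log_ok <- tibble::tibble(stim_id = 1L, detection_time_s = 60,
                           delay_s = 0, delay_class = "0", light_on_s = 60,
                           light_duration_s = 10, triggered = TRUE,
                           condition = "PV_ChR2")
  gated <- gate_pre_stimulation(model, s2, log_ok)
  expect_true(gated$gate_pass)
  expect_equal(gated$pre_label, "S2_ICTAL")
  base <- fixture_state_recording("BASELINE", duration = 120, seed = 22)
  expect_false(gate_pre_stimulation(model, base, log_ok)$gate_pass)
  # insufficient pre-trigger data rejects the trial
  early <- dplyr::mutate(log_ok, detection_time_s = 4)
  expect_false(gate_pre_stimulation(model, s2, early)$gate_pass)
})

test_that("tidy and glance methods return the documented shapes", {
  fit <- fixture_model()
  ti <- tidy(fit)
  expect_equal(nrow(ti), 20)
  expect_true(all(ti$importance >= 0))
  gl <- glance(fit)
  expect_equal(gl$n_classes, 4)
  expect_equal(gl$num_trees, 200)
})
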