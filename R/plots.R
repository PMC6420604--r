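#' Plot an ECoG recording with its state annotation
#'
#' Downsampled trace (min/max envelope per bin, so spikes stay visible) with
#' ground-truth state intervals shaded when present.
#'
#' @param object An [ecog_recording()].
#' @param max_points Approximate number of plotted envelope bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ecog_recording <- function(object, max_points = 4000, ...) {
  x <- object$samples
  fs <- object$sampling_rate
  bin <- max(1L, floor(length(x) / max_points))
  nb <- floor(length(x) / bin)
  idx <- rep(seq_len(nb), each = bin)
  xs <- x[seq_len(nb * bin)]
  env <- tibble(
    t = (seq_len(nb) - 0.5) * bin / fs,
    lo = as.numeric(tapply(xs, idx, min)),
    hi = as.numeric(tapply(xs, idx, max))
  )
  g <- ggplot2::ggplot(env)
  ivs <- state_intervals(object)
  if (nrow(ivs)) {
    g <- g + ggplot2::geom_rect(
      data = ivs,
      ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                   ymin = -Inf, ymax = Inf, fill = .data$state),
      alpha = 0.15
    )
  }
  g +
    ggplot2::geom_linerange(ggplot2::aes(x = .data$t, ymin = .data$lo,
                                         ymax = .data$hi),
                            linewidth = 0.2) +
    ggplot2::labs(x = "time (s)",
                  y = if (object$scaled) "scaled ECoG" else "ECoG (uV)",
                  fill = "state", title = object$animal_id) +
    ggplot2::theme_minimal()
}

#' 3-D LDA projection, plotted as discriminant pairs
#'
#' Scatter of the epochs in the space of the first linear discriminants,
#' one panel per discriminant pair, coloured by network state.
#'
#' @param projection Output of [lda_project()].
#' @return A ggplot object.
#' @export
plot_lda_projection <- function(projection) {
  lds <- grep("^LD", names(projection), value = TRUE)
  pairs <- utils::combn(lds, 2)
  long <- bind_rows(lapply(seq_len(ncol(pairs)), function(k) {
    tibble(
      panel = paste(pairs[1, k], "vs", pairs[2, k]),
      x = projection[[pairs[1, k]]],
      y = projection[[pairs[2, k]]],
      label = projection$label
    )
  }))
  ggplot2::ggplot(long, ggplot2::aes(.data$x, .data$y,
                                     colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.7, size = 1) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL, colour = "state") +
    ggplot2::theme_minimal()
}

#' One-vs-rest ROC curves of a classifier evaluation
#'
#' @param eval A `classifier_eval` from [evaluate_state_classifier()].
#' @return A ggplot object.
#' @export
plot_roc <- function(eval) {
  ggplot2::ggplot(eval$roc, ggplot2::aes(.data$fpr, .data$tpr,
                                         colour = .data$class)) +
    ggplot2::geom_path() +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey50") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "FP rate", y = "TP rate", colour = "state") +
    ggplot2::theme_minimal()
}

#' Plot a pre/during/post window analysis
#'
#' Group mean +- s.e.m. of event durations per 10-s window, with per-animal
#' means overlaid.
#'
#' @param object A `window_result` from [window_analysis()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.window_result <- function(object, ...) {
  pa <- mutate(object$per_animal,
               window = factor(.data$window, c("pre", "during", "post")))
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(.data$window, .data$mean_duration_s)) +
    ggplot2::geom_col(fill = "grey80", width = 0.6) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_duration_s - .data$sem_duration_s,
                   ymax = .data$mean_duration_s + .data$sem_duration_s),
      width = 0.15
    ) +
    ggplot2::geom_jitter(data = pa, width = 0.08, alpha = 0.6, size = 1.5) +
    ggplot2::labs(x = NULL, y = "mean discharge duration (s)") +
    ggplot2::theme_minimal()
}

#' Plot a group normalized-duration result
#'
#' Per-animal mean normalized durations with the group mean +- s.e.m.; the
#' dashed line marks 100% (no effect).
#'
#' @param object A `group_result` from [group_normalized_duration()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.group_result <- function(object, ...) {
  pa <- object$per_animal
  ggplot2::ggplot(pa, ggplot2::aes(x = "group",
                                   y = .data$mean_normalized_pct)) +
    ggplot2::geom_hline(yintercept = 100, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_jitter(width = 0.05, alpha = 0.7) +
    ggplot2::annotate("pointrange", x = 1.2, y = object$mean_pct,
                      ymin = object$mean_pct - object$sem_pct,
                      ymax = object$mean_pct + object$sem_pct,
                      colour = "firebrick") +
    ggplot2::labs(x = NULL, y = "normalized seizure duration (%)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
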