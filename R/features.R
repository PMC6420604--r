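#' The fixed 20-feature set
#'
#' Names, in order, of the per-epoch features used by the network-state
#' classifier.
#' @return Character vector of length 20.
#' @export
feature_names <- function() {
  c("mean", "std", "kurtosis", "skew", "sum_abs_diff",
    "n_peaks", "n_valleys", "mean_valley", "mean_peak",
    "mean_peak_valley_range",
    "wpow_1", "wpow_5", "wpow_10", "wpow_15", "wpow_20",
    "wpow_30", "wpow_60", "wpow_90",
    "n_baseline_points", "baseline_idx_mean_diff")
}

wavelet_freqs <- function() c(1, 5, 10, 15, 20, 30, 60, 90)

#' Min-max scale a recording to [0, 1]
#'
#' Scaling is per recording (not per epoch), so features are invariant to any
#' affine transform of the raw voltages. A constant signal maps to all zeros.
#' Idempotent.
#'
#' @param recording An [ecog_recording()] with at least 2 samples.
#' @return The recording with samples in `[0, 1]` and `scaled = TRUE`.
#' @export
minmax_scale <- function(recording) {
  stopifnot(inherits(recording, "ecog_recording"))
  if (length(recording$samples) < 2) abort("Need at least 2 samples to scale.")
  rng <- range(recording$samples)
  recording$samples <- if (rng[2] > rng[1]) {
    (recording$samples - rng[1]) / (rng[2] - rng[1])
  } else {
    rep(0, length(recording$samples))
  }
  recording$scaled <- TRUE
  recording
}

#' Cut a recording into consecutive 10-s epochs
#'
#' Non-overlapping consecutive epochs of exactly `epoch_s` seconds; a final
#' partial epoch is discarded. Epochs inherit a ground-truth state label when
#' they fall entirely inside one annotated state interval.
#'
#' @param recording A (scaled) [ecog_recording()].
#' @param epoch_s Epoch length in seconds (default 10).
#' @return A tibble with columns `animal_id`, `epoch_id`, `start_s`, `label`
#'   and a list-column `samples`.
#' @export
segment_epochs <- function(recording, epoch_s = 10) {
  stopifnot(inherits(recording, "ecog_recording"))
  fs <- recording$sampling_rate
  len <- round(epoch_s * fs)
  k <- floor(length(recording$samples) / len)
  if (k < 1) {
    return(tibble(animal_id = character(), epoch_id = integer(),
                  start_s = numeric(), label = character(),
                  samples = list()))
  }
  starts <- (seq_len(k) - 1) * epoch_s
  ivs <- state_intervals(recording)
  lab <- vapply(starts, function(s) {
    hit <- which(ivs$start_s <= s + 1e-9 & ivs$end_s >= s + epoch_s - 1e-9)
    if (length(hit) == 1) ivs$state[hit] else NA_character_
  }, character(1))
  tibble(
    animal_id = recording$animal_id,
    epoch_id = seq_len(k),
    start_s = starts,
    label = lab,
    samples = lapply(seq_len(k), function(i) {
      recording$samples[((i - 1) * len + 1):(i * len)]
    })
  )
}

#' Peaks and valleys by topographic prominence
#'
#' Peaks are local maxima whose topographic prominence is at least
#' `prominence`; valleys are peaks of the negated signal.
#'
#' @param x Numeric vector (one epoch of samples).
#' @param prominence Minimum prominence, in the signal's (scaled) units.
#' @return A list with integer vectors `peaks` and `valleys` (1-based).
#' @export
detect_extrema <- function(x, prominence = 0.05) {
  if (prominence < 0) abort("`prominence` must be >= 0.")
  find <- function(v) {
    idx <- local_maxima_cpp(v)
    if (!length(idx)) return(integer(0))
    idx[peak_prominence_cpp(v, idx) >= prominence]
  }
  list(peaks = find(x), valleys = find(-x))
}

#' Baseline-point features
#'
#' Baseline points are samples within `band` of the epoch median. Returns the
#' count and the mean first-difference of their (sorted) indices; with fewer
#' than two baseline points the mean index difference defaults to the epoch
#' length.
#'
#' @inheritParams detect_extrema
#' @param band Half-width of the baseline band around the median (> 0).
#' @return Named numeric vector `c(n_baseline_points, baseline_idx_mean_diff)`.
#' @export
baseline_points <- function(x, band = 0.02) {
  if (band <= 0) abort("`band` must be positive.")
  idx <- which(abs(x - median(x)) <= band)
  md <- if (length(idx) < 2) length(x) else mean(diff(idx))
  c(n_baseline_points = length(idx), baseline_idx_mean_diff = md)
}

# Precomputed frequency-domain Morlet filters for epochs of fixed length.
# L2-normalised (sum |psi|^2 = 1), centre frequency f = w0 / (2 pi scale).
morlet_plan <- function(n, sampling_rate, freqs = wavelet_freqs(), w0 = 6) {
  scales <- w0 * sampling_rate / (2 * pi * freqs)      # in samples
  kmax <- ceiling(4 * max(scales))
  m <- stats::nextn(n + 2 * kmax + 1, c(2, 3, 5))
  filters <- lapply(scales, function(s) {
    kk <- ceiling(4 * s)
    k <- c(0:kk, -(kk:1))
    psi <- pi^(-1 / 4) / sqrt(s) * exp(1i * w0 * k / s - k^2 / (2 * s^2))
    vec <- complex(m)
    vec[c(1:(kk + 1), (m - kk + 1):m)] <- psi
    Conj(fft(vec))
  })
  list(n = n, m = m, freqs = freqs, filters = filters)
}

# Mean squared Morlet coefficient magnitude per centre frequency, divided by
# the centre frequency (the 1/f-normalised convention: white-noise power
# decays with frequency).
morlet_power <- function(x, plan) {
  xp <- complex(real = c(x, numeric(plan$m - length(x))))
  X <- fft(xp)
  vapply(seq_along(plan$freqs), function(i) {
    w <- fft(X * plan$filters[[i]], inverse = TRUE) / plan$m
    mean(Mod(w[seq_len(plan$n)])^2) / plan$freqs[i]
  }, numeric(1))
}

#' Extract the 20 features from one epoch
#'
#' Computes, in fixed order: mean, standard deviation, excess kurtosis,
#' adjusted Fisher-Pearson skew, sum of absolute first differences, numbers
#' of prominent peaks and valleys, mean valley and peak values and their
#' difference, the eight 1/f-normalised Morlet wavelet powers at 1-90 Hz, and
#' the two baseline-point features. Degenerate epochs (constant, or without
#' extrema) fall back to declared conventions: zero skew/kurtosis, and
#' peak/valley means equal to the epoch mean.
#'
#' @param x Numeric vector, one (scaled) epoch.
#' @param sampling_rate Hz.
#' @param prominence Peak/valley prominence threshold (scaled units).
#' @param baseline_band Baseline band half-width (scaled units).
#' @param plan Optional precomputed [morlet_plan()] (internal reuse).
#' @return Named numeric vector of length 20 (see [feature_names()]).
#' @export
extract_features <- function(x, sampling_rate = 512, prominence = 0.05,
                             baseline_band = 0.02, plan = NULL) {
  if (is.null(plan)) plan <- morlet_plan(length(x), sampling_rate)
  s <- sd(x)
  ext <- detect_extrema(x, prominence)
  mp <- if (length(ext$peaks)) mean(x[ext$peaks]) else mean(x)
  mv <- if (length(ext$valleys)) mean(x[ext$valleys]) else mean(x)
  bp <- baseline_points(x, baseline_band)
  out <- c(
    mean = mean(x),
    std = s,
    kurtosis = if (s > 0) e1071::kurtosis(x, type = 2) else 0,
    skew = if (s > 0) e1071::skewness(x, type = 2) else 0,
    sum_abs_diff = sum(abs(diff(x))),
    n_peaks = length(ext$peaks),
    n_valleys = length(ext$valleys),
    mean_valley = mv,
    mean_peak = mp,
    mean_peak_valley_range = mp - mv,
    setNames(morlet_power(x, plan), paste0("wpow_", wavelet_freqs())),
    bp
  )
  stopifnot(identical(names(out), feature_names()))
  out
}

#' Epoch-feature matrix for a recording
#'
#' Min-max scales the recording (if not already scaled), cuts it into 10-s
#' epochs and extracts the 20 features for each: the tabular interface to the
#' classifier.
#'
#' @param recording An [ecog_recording()].
#' @inheritParams extract_features
#' @param epoch_s Epoch length in seconds.
#' @return A tibble: `animal_id`, `epoch_id`, `start_s`, `label`, then the 20
#'   feature columns.
#' @export
epoch_features <- function(recording, epoch_s = 10, prominence = 0.05,
                           baseline_band = 0.02) {
  if (!recording$scaled) recording <- minmax_scale(recording)
  eps <- segment_epochs(recording, epoch_s)
  if (!nrow(eps)) {
    fm <- matrix(numeric(0), 0, 20, dimnames = list(NULL, feature_names()))
    return(bind_cols(eps[, c("animal_id", "epoch_id", "start_s", "label")],
                     as_tibble(fm)))
  }
  plan <- morlet_plan(length(eps$samples[[1]]), recording$sampling_rate)
  fm <- t(vapply(eps$samples, extract_features, numeric(20),
                 sampling_rate = recording$sampling_rate,
                 prominence = prominence, baseline_band = baseline_band,
                 plan = plan))
  bind_cols(eps[, c("animal_id", "epoch_id", "start_s", "label")],
            as_tibble(fm))
}
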