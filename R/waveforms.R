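#' Waveform parameters for synthetic epileptiform events
#'
#' Phenomenological shape parameters for the generated signal. Discrete
#' seizures open with a large negative sentinel spike and continue as a train
#' of smaller negative discharge spikes carrying a high-frequency oscillatory
#' component; interictal (State 1) bursts are single brief discharges of
#' 100-150 ms; the background is 1/f (pink) noise. Amplitudes are chosen so
#' that sentinel spikes exceed 6x the baseline noise SD (calibratable
#' threshold detection) while body and burst spikes stay between the offline
#' segmentation threshold (~4x) and the online detection threshold (~6x).
#'
#' @param sentinel_amplitude Sentinel trough amplitude, microvolts (negative).
#' @param sentinel_width_s Sentinel half-sine width, seconds.
#' @param body_spike_rate Discharge-spike rate inside a seizure body, Hz.
#' @param body_spike_amplitude Body/burst spike trough amplitude, microvolts
#'   (negative).
#' @param hf_band High-frequency component band, Hz `(low, high)`.
#' @param hf_amplitude SD of the band-limited high-frequency component,
#'   microvolts.
#' @param burst_len_range State-1 burst length range, seconds.
#' @param baseline_noise_sd Pink-noise SD, microvolts.
#' @return A `seizure_waveform_params` list.
#' @export
seizure_waveform_params <- function(sentinel_amplitude = -320,
                                    sentinel_width_s = 0.06,
                                    body_spike_rate = 10,
                                    body_spike_amplitude = -220,
                                    hf_band = c(60, 120),
                                    hf_amplitude = 18,
                                    burst_len_range = c(0.100, 0.150),
                                    baseline_noise_sd = 25) {
  if (sentinel_amplitude >= 0) abort("`sentinel_amplitude` must be negative.")
  if (length(hf_band) != 2 || hf_band[1] <= 0 || hf_band[2] <= hf_band[1]) {
    abort("`hf_band` must be an increasing positive pair (Hz).")
  }
  structure(
    list(
      sentinel_amplitude = sentinel_amplitude,
      sentinel_width_s = sentinel_width_s,
      body_spike_rate = body_spike_rate,
      body_spike_amplitude = body_spike_amplitude,
      hf_band = hf_band,
      hf_amplitude = hf_amplitude,
      burst_len_range = burst_len_range,
      baseline_noise_sd = baseline_noise_sd
    ),
    class = "seizure_waveform_params"
  )
}

# 1/f-shaped Gaussian noise with the requested SD, via spectral shaping.
# Pads to a highly composite FFT length and truncates.
pink_noise <- function(n, sd = 1) {
  if (n <= 1) return(rnorm(n, 0, sd))
  m <- stats::nextn(n, c(2, 3, 5))
  w <- rnorm(m)
  spec <- fft(w)
  f <- c(1, seq_len(m - 1))                      # avoid the DC singularity
  f <- pmin(f, m - f + 1)                        # mirror for negative freqs
  spec <- spec / sqrt(f)
  x <- Re(fft(spec, inverse = TRUE)) / m
  x <- x[seq_len(n)]
  x <- x - mean(x)
  s <- sd(x)
  if (s > 0) x <- x * (sd / s)
  x
}

# Negative half-sine spike of `width_s`, trough = `amplitude` (< 0).
neg_spike <- function(amplitude, width_s, sampling_rate) {
  nw <- max(2L, round(width_s * sampling_rate))
  amplitude * sin(pi * seq(0, 1, length.out = nw))
}

# Band-limited Gaussian noise (the seizure high-frequency component).
hf_component <- function(n, band, amplitude, sampling_rate) {
  if (n < 24 || amplitude <= 0) return(numeric(n))
  ny <- sampling_rate / 2
  w <- pmin(band / ny, 0.99)
  bf <- signal::butter(3, w, type = "pass")
  x <- signal::filtfilt(bf, rnorm(n))
  s <- sd(x)
  if (s > 0) x <- x * (amplitude / s)
  x
}

#' Synthesize one ictal discharge
#'
#' Builds one discrete electrographic seizure: a large negative sentinel
#' spike at onset (the most negative sample of the event, used for online
#' threshold detection), followed by a body of repetitive negative discharge
#' spikes riding on a band-limited high-frequency component. Durations at or
#' below the sentinel width yield a sentinel-only event.
#'
#' @param duration Event duration in seconds (> 0).
#' @param params A [seizure_waveform_params()].
#' @param sampling_rate Hz.
#' @param seed Optional integer seed; when `NULL` the ambient RNG stream is
#'   used (as when called from [generate_recording()]).
#' @return Numeric vector of `round(duration * sampling_rate)` samples
#'   (microvolts, zero-centred; add to background noise).
#' @export
generate_seizure_waveform <- function(duration,
                                      params = seizure_waveform_params(),
                                      sampling_rate = 512, seed = NULL) {
  if (duration <= 0) abort("`duration` must be positive.")
  if (!is.null(seed)) {
    return(withr::with_seed(seed,
      generate_seizure_waveform(duration, params, sampling_rate, seed = NULL)))
  }
  n <- max(2L, round(duration * sampling_rate))
  x <- numeric(n)
  sent <- neg_spike(params$sentinel_amplitude * runif(1, 0.95, 1.1),
                    params$sentinel_width_s, sampling_rate)
  ns <- min(n, length(sent))
  x[seq_len(ns)] <- sent[seq_len(ns)]
  body_start <- params$sentinel_width_s + 0.02
  if (duration > body_start + 0.05) {
    # discharge-spike train through to just before the event end
    times <- seq(body_start, duration - 0.05, by = 1 / params$body_spike_rate)
    times <- times + runif(length(times), -0.015, 0.015)
    times <- times[times > body_start & times < duration - 0.03]
    # cap body spikes well below the sentinel so the sentinel stays the
    # arg-min of the event
    amps <- params$body_spike_amplitude * runif(length(times), 0.9, 1.1)
    amps <- pmax(amps, 0.78 * params$sentinel_amplitude)
    for (k in seq_along(times)) {
      sp <- neg_spike(amps[k], 0.04, sampling_rate)
      i0 <- round(times[k] * sampling_rate) + 1L
      idx <- i0:min(n, i0 + length(sp) - 1L)
      x[idx] <- x[idx] + sp[seq_along(idx)]
    }
    i1 <- round(body_start * sampling_rate) + 1L
    hf <- hf_component(n - i1 + 1L, params$hf_band, params$hf_amplitude,
                       sampling_rate)
    x[i1:n] <- x[i1:n] + hf
  }
  x
}

# One State-1 interictal burst: a single brief discharge (100-150 ms),
# below the online detection threshold.
burst_waveform <- function(len_s, params, sampling_rate) {
  neg_spike(0.6 * params$body_spike_amplitude * runif(1, 0.9, 1.1),
            len_s, sampling_rate)
}

# Continuous epileptiform activity (State 3): an open-ended discharge train
# with the high-frequency component, no sentinel.
continuous_activity <- function(duration, params, sampling_rate) {
  n <- max(2L, round(duration * sampling_rate))
  x <- numeric(n)
  times <- seq(0.05, duration - 0.05, by = 1 / params$body_spike_rate)
  if (length(times)) {
    times <- times + runif(length(times), -0.02, 0.02)
    times <- times[times > 0 & times < duration - 0.03]
    for (tk in times) {
      sp <- neg_spike(params$body_spike_amplitude * runif(1, 0.85, 1.15),
                      0.04, sampling_rate)
      i0 <- round(tk * sampling_rate) + 1L
      idx <- i0:min(n, i0 + length(sp) - 1L)
      x[idx] <- x[idx] + sp[seq_along(idx)]
    }
  }
  x + hf_component(n, params$hf_band, params$hf_amplitude, sampling_rate)
}
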