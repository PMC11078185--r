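#' Robust noise-SD estimate from a coefficient band
#'
#' `sigma = median(|c|) / 0.6745`, where 0.6745 is the 75th percentile of
#' the standard normal distribution: under pure Gaussian noise the median
#' absolute coefficient equals `0.6745 * sigma`, so the ratio is a robust
#' estimator of the noise SD that large, sparse signal coefficients barely
#' perturb.
#'
#' @param coeffs numeric coefficient band (or any zero-mean series).
#' @return The estimated noise SD.
#' @export
estimate_sigma <- function(coeffs) {
  if (length(coeffs) == 0L) stop("empty coefficient band")
  median(abs(coeffs)) / 0.6745
}

#' Universal (Donoho-Johnstone) threshold
#'
#' `Th = sigma * sqrt(2 * ln(N))`: with probability tending to one, the
#' maximum of N iid Gaussian noise coefficients stays below this bound, so
#' hard-thresholding at Th suppresses pure noise.
#'
#' @param sigma noise SD (>= 0).
#' @param n_samples number of samples N in the coefficient band (>= 1).
#' @return The threshold Th.
#' @examples
#' universal_threshold(1, 1000)  # sqrt(2 log 1000) ~= 3.71692
#' @export
universal_threshold <- function(sigma, n_samples) {
  if (any(n_samples < 1)) stop("n_samples must be >= 1")
  if (any(sigma < 0)) stop("sigma must be >= 0")
  sigma * sqrt(2 * log(n_samples))
}

#' Hard thresholding
#'
#' Keeps coefficients whose magnitude strictly exceeds the threshold and
#' zeroes the rest; `|x| = Th` maps to 0.
#'
#' @param x numeric coefficients.
#' @param threshold non-negative threshold.
#' @return Thresholded coefficients.
#' @export
hard_threshold <- function(x, threshold) {
  if (!is.finite(threshold)) stop("threshold must be finite")
  x * (abs(x) > threshold)
}

#' Wavelet denoising by level-wise universal hard thresholding
#'
#' Decomposes the signal with a 3-level Daubechies-5 transform (stationary
#' by default), estimates the noise SD of each detail band with
#' [estimate_sigma()], hard-thresholds that band at its own universal
#' threshold, and reconstructs. The approximation band is never
#' thresholded. Output length equals input length.
#'
#' @param x numeric single-channel series (microvolts).
#' @param levels decomposition levels (default 3).
#' @param variant `"stationary"` (undecimated, default) or `"decimated"`.
#' @param thresholds optional numeric vector of per-level thresholds
#'   overriding the universal rule (recycled over levels); `0` reproduces
#'   the transform round trip.
#' @return The denoised series, with attributes `sigma` and `thresholds`
#'   (per level, finest first).
#' @export
denoise <- function(x, levels = 3, variant = c("stationary", "decimated"),
                    thresholds = NULL) {
  variant <- match.arg(variant)
  if (anyNA(x)) stop("signal contains NA")
  decomp <- if (variant == "stationary") swt_db5(x, levels)
            else dwt_db5(x, levels)
  sig <- vapply(decomp$details, estimate_sigma, numeric(1))
  th <- if (is.null(thresholds)) {
    vapply(seq_len(levels), function(l)
      universal_threshold(sig[l], length(decomp$details[[l]])), numeric(1))
  } else rep_len(thresholds, levels)
  for (l in seq_len(levels))
    decomp$details[[l]] <- hard_threshold(decomp$details[[l]], th[l])
  y <- if (variant == "stationary") iswt_db5(decomp) else idwt_db5(decomp)
  attr(y, "sigma") <- sig
  attr(y, "thresholds") <- th
  y
}

#' Detection threshold of a (denoised) series
#'
#' The universal threshold computed from the series itself: noise SD by the
#' robust median rule, N the series length. Applied to the reconstructed
#' (denoised) signal this gives the spike-detection threshold.
#'
#' @param x numeric series.
#' @return The detection threshold in the units of `x`.
#' @export
detection_threshold <- function(x) {
  universal_threshold(estimate_sigma(x), length(x))
}

#' Extract the cardiac component of a channel
#'
#' Continuous-wavelet decomposition with a Ricker kernel at a 5-ms scale;
#' the response isolates QRS-like transients, whose local maxima mark beat
#' times.
#'
#' @param x numeric single-channel series.
#' @param sample_rate sampling rate in Hz.
#' @param scale_ms Ricker scale (full central-lobe width), default 5 ms.
#' @return The cardiac component series (same length as `x`).
#' @export
extract_cardiac <- function(x, sample_rate, scale_ms = 5) {
  cwt_ricker(x, sample_rate, scale_ms)
}

#' Detect spikes on a denoised series
#'
#' Local maxima whose amplitude strictly exceeds the detection threshold,
#' thinned so that accepted peaks are at least the refractory period apart
#' (when two candidates compete, the larger wins). A 4-ms waveform window
#' centred on each peak is extracted; windows clipped by the recording edge
#' are zero-padded and flagged.
#'
#' @param x numeric denoised series (microvolts).
#' @param sample_rate sampling rate in Hz.
#' @param threshold detection threshold; default [detection_threshold()] of
#'   `x` itself.
#' @param refractory_ms minimum peak separation (default 4 ms).
#' @param window_ms waveform window length (default 4 ms).
#' @param polarity `"positive"` (default; evoked potentials are time-locked
#'   positive waveforms) or `"signed"` (detect on `|x|`).
#' @return A list with `spikes`: data.frame (`peak_index` 1-based,
#'   `peak_time_s`, `peak_amplitude_uV`, `edge`), and `waveforms`: spikes x
#'   window matrix. Zero spikes yields empty components, not an error.
#' @export
detect_spikes <- function(x, sample_rate, threshold = NULL,
                          refractory_ms = 4, window_ms = 4,
                          polarity = c("positive", "signed")) {
  polarity <- match.arg(polarity)
  if (is.null(threshold)) threshold <- detection_threshold(x)
  v <- if (polarity == "signed") abs(x) else x
  n <- length(v)
  nw <- round(window_ms / 1000 * sample_rate)
  empty <- list(spikes = data.frame(peak_index = integer(0),
                                    peak_time_s = numeric(0),
                                    peak_amplitude_uV = numeric(0),
                                    edge = logical(0)),
                waveforms = matrix(numeric(0), 0, nw))
  if (n < 3L) return(empty)
  core <- v[2:(n - 1L)]
  is_peak <- core > v[1:(n - 2L)] & core >= v[3:n] & core > threshold
  cand <- which(is_peak) + 1L
  if (!length(cand)) return(empty)
  # greedy refractory thinning, larger peaks first
  refr <- refractory_ms / 1000 * sample_rate
  ord <- cand[order(v[cand], decreasing = TRUE)]
  accepted <- integer(0)
  for (i in ord) {
    if (!length(accepted) || all(abs(accepted - i) >= refr))
      accepted <- c(accepted, i)
  }
  accepted <- sort(accepted)
  half <- nw %/% 2L
  waves <- matrix(0, length(accepted), nw)
  edge <- logical(length(accepted))
  for (j in seq_along(accepted)) {
    idx <- (accepted[j] - half):(accepted[j] - half + nw - 1L)
    keep <- idx >= 1L & idx <= n
    edge[j] <- !all(keep)
    waves[j, keep] <- x[idx[keep]]
  }
  list(spikes = data.frame(peak_index = accepted,
                           peak_time_s = (accepted - 1L) / sample_rate,
                           peak_amplitude_uV = x[accepted],
                           edge = edge),
       waveforms = waves)
}
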