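test_that("the robust sigma estimator matches its defining examples", {
  expect_equal(estimate_sigma(c(0.6745, -0.6745, 0.6745)), 1.0)
  expect_equal(estimate_sigma(numeric(5)), 0)
  expect_error(estimate_sigma(numeric(0)), "empty")
  set.seed(21)
  expect_true(abs(estimate_sigma(rnorm(1e5, sd = 2)) - 2) < 0.04)
})

test_that("the universal threshold follows its closed form", {
  expect_equal(universal_threshold(1, 1), 0)
  expect_equal(universal_threshold(0, 12345), 0)
  expect_equal(universal_threshold(1, 1000), 3.71692218884984,
               tolerance = 1e-12)
  for (sigma in c(0.1, 1, 7.5)) {
    for (n in c(2, 100, 1e6)) {
      expect_equal(universal_threshold(sigma, n), sigma * sqrt(2 * log(n)))
    }
  }
  expect_error(universal_threshold(1, 0), "n_samples")
})

test_that("hard thresholding keeps only strictly supra-threshold values", {
  expect_equal(hard_threshold(5, 0), 5)
  expect_equal(hard_threshold(2, 2), 0)   # |x| = Th maps to 0
  expect_equal(hard_threshold(c(-3, 0.5, 2, -0.9), 1), c(-3, 0, 2, 0))
})

test_that("denoising reconstructs exactly at zero threshold and scales", {
  set.seed(22)
  x <- rnorm(1e5)
  expect_lt(max(abs(denoise(x, thresholds = 0) - x)),
            1e-6 * diff(range(x)))
  expect_equal(denoise(numeric(200)), numeric(200),
               ignore_attr = TRUE)
  # scale equivariance: sigma and thresholds both scale with the signal
  a <- 3.7
  expect_equal(as.numeric(denoise(a * x)), a * as.numeric(denoise(x)),
               tolerance = 1e-10)
  expect_error(denoise(c(1, NA, 2)), "NA")
})

test_that("universal hard thresholding suppresses pure noise", {
  set.seed(23)
  x <- rnorm(1e5)
  for (variant in c("stationary", "decimated")) {
    y <- denoise(x, variant = variant)
    expect_lt(var(y) / var(x), 0.15)
  }
})

test_that("a strong ECAP survives denoising with its amplitude intact", {
  fs <- 10000
  set.seed(24)
  n <- 20000
  w <- ecap_template(fs)
  x <- rnorm(n, sd = 2)
  centre <- 10000
  idx <- centre + seq_along(w) - (length(w) + 1) / 2
  clean <- numeric(n)
  clean[idx] <- 100 * w   # amplitude far above the noise floor
  y <- denoise(x + clean)
  expect_lt(abs(max(y[idx]) - 100) / 100, 0.20)
})

test_that("spike detection matches ground truth on a noiseless session", {
  cfg <- noiseless_config(duration_s = 6)
  s <- simulate_session(cfg)
  den <- denoise_recording(s$recording)
  truth <- s$truth
  clean_amp <- attr(truth, "clean_amplitudes")
  for (ch in c(15, 17, 20)) {
    x <- den$data[ch, ]
    det <- detect_spikes(x, cfg$sample_rate, threshold = 1)
    supra <- which(clean_amp[, ch] > 2)
    for (e in supra) {
      dt <- abs(det$spikes$peak_time_s - truth$peak_time_s[e])
      expect_lte(min(dt) * cfg$sample_rate, 1)   # within one sample
    }
  }
})

test_that("detection respects threshold and refractory rules", {
  fs <- 10000
  expect_equal(nrow(detect_spikes(rep(0.5, 1000), fs,
                                  threshold = 1)$spikes), 0)
  # two peaks 1 ms apart with a 4-ms refractory: only the larger survives
  x <- numeric(1000)
  x[100] <- 5
  x[110] <- 3
  det <- detect_spikes(x, fs, threshold = 1, refractory_ms = 4)
  expect_equal(det$spikes$peak_index, 100)
  expect_equal(det$spikes$peak_amplitude_uV, 5)
  # brute-force oracle: largest-first greedy selection with separation
  set.seed(25)
  y <- rnorm(5000)
  th <- 2
  det2 <- detect_spikes(y, fs, threshold = th, refractory_ms = 2)
  cand <- which(diff(sign(diff(y))) < 0) + 1L
  cand <- cand[y[cand] > th]
  keep <- integer(0)
  for (i in cand[order(y[cand], decreasing = TRUE)]) {
    if (!length(keep) || all(abs(keep - i) >= 2 / 1000 * fs))
      keep <- c(keep, i)
  }
  expect_setequal(det2$spikes$peak_index, keep)
  # windows are 4 ms long; edge windows flagged and zero-padded
  z <- numeric(200)
  z[3] <- 9
  detz <- detect_spikes(z, fs, threshold = 1)
  expect_equal(ncol(detz$waveforms), round(0.004 * fs))
  expect_true(detz$spikes$edge[1])
})

test_that("the cardiac extractor locates synthetic heart beats", {
  fs <- 10000
  dur <- 30
  set.seed(26)
  n <- dur * fs
  beat_times <- seq(0.2, dur - 0.2, by = 1 / 6)   # 6-Hz ECG train
  x <- rnorm(n, sd = 3)
  a_s <- 0.0025                                    # 5-ms central lobe
  half <- round(3 * a_s * fs)
  kern <- 30 * ricker_wavelet((-half:half) / fs, a_s)
  for (b in beat_times) {
    i <- round(b * fs) + 1L
    x[(i - half):(i + half)] <- x[(i - half):(i + half)] + kern
  }
  resp <- extract_cardiac(x, fs, scale_ms = 5)
  det <- detect_spikes(resp, fs, threshold = max(resp) / 3,
                       refractory_ms = 80)
  hit <- vapply(beat_times, function(b)
    any(abs(det$spikes$peak_time_s - b) <= 0.002), logical(1))
  expect_gte(mean(hit), 0.9)
})
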