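test_that("peak amplitude maps follow the generator's gain structure", {
  cfg <- noiseless_config(duration_s = 6)
  s <- simulate_session(cfg)
  den <- denoise_recording(s$recording)
  spikes <- detect_session(den, threshold = 2)
  ep <- epoch(den, s$events, c(0, 0.02))
  map <- peak_amplitudes(ep, spikes)
  clean <- attr(s$truth, "clean_amplitudes")
  supra <- clean > 4    # channels whose clean peak clears the threshold
  expect_equal(dim(map), dim(clean))
  expect_lt(max(abs(map[supra] - clean[supra]) / clean[supra]), 0.2)
  expect_true(all(map[clean < 1.8] == 0))

  # no spikes anywhere: all-zero map
  none <- spikes[0, , drop = FALSE]
  expect_true(all(peak_amplitudes(ep, none) == 0))

  # two spikes in one window: the larger is recorded
  two <- data.frame(channel = c(1, 1),
                    peak_time_s = s$events$time_s[1] + c(0.001, 0.003),
                    peak_amplitude_uV = c(3, 8))
  expect_equal(peak_amplitudes(ep, two)[1, 1], 8)
})

test_that("topoframes interpolate linearly through the electrode values", {
  lay <- make_layout(4)   # electrodes at -180, -90, 0, 90
  fr <- build_topoframe(c(1, 1, 1, 1), lay)
  expect_true(all(fr$amplitude_uV == 1))

  fr2 <- build_topoframe(c(0, 2, 4, 0), lay, grid_step_deg = 1)
  # midpoint between -90 (value 2) and 0 (value 4) is 3
  expect_equal(fr2$amplitude_uV[fr2$angle_deg == -45], 3)
  # frame passes through the data
  for (i in 1:4)
    expect_equal(fr2$amplitude_uV[fr2$angle_deg == lay$angles_deg[i]],
                 c(0, 2, 4, 0)[i])
  # linear scheme stays inside the data range (wrap included)
  expect_gte(min(fr2$amplitude_uV), 0)
  expect_lte(max(fr2$amplitude_uV), 4)
  expect_error(build_topoframe(c(1, 2, 3, 4), lay, grid_step_deg = 0),
               "grid step")
})

test_that("hotspots are recovered within one electrode spacing", {
  lay <- make_layout(32)
  spacing <- 360 / 32
  for (rot in seq(0, 350, by = 10)) {
    p <- default_source_profiles(rot)
    fr <- build_topoframe(50 * source_gains(p$SSEP_L, lay), lay)
    h <- find_hotspot(fr)
    expect_true(h$found)
    err <- abs(wrap_angle(h$angle_deg - wrap_angle(25 + rot)))
    expect_lte(err, spacing)
  }
  # dual-hotspot motor profile: both bumps recovered
  p <- default_source_profiles()
  frm <- build_topoframe(50 * source_gains(p$MEP_L, lay), lay)
  h2 <- find_hotspot(frm, n_hotspots = 2)
  got <- sort(c(h2$angle_deg, h2$secondary_angle_deg))
  expect_lte(abs(got[1] - 90), spacing)
  expect_lte(abs(got[2] - 140), spacing)
  # flat frame: flagged, not an error
  flat <- build_topoframe(rep(3, 32), lay)
  expect_false(find_hotspot(flat)$found)
})

test_that("temporal evolution tracks a hotspot that moves after stimulus", {
  fs <- 10000
  lay <- make_layout(32)
  nw <- round(0.008 * fs)
  # synthetic epochs: dorsal hotspot for 4 ms, then ventrolateral
  g1 <- source_gains(source_profile("SSEP_L", 20, 12), lay)
  g2 <- source_gains(source_profile("MEP_L", 140, 12), lay)
  arr <- array(0, c(2, 32, nw))
  half <- nw / 2
  for (e in 1:2) {
    arr[e, , seq_len(half)] <- g1 %o% rep(10, half)
    arr[e, , half + seq_len(half)] <- g2 %o% rep(10, half)
  }
  ep <- structure(list(data = arr,
                       events = event_table(c(1, 2), c("SSEP_L", "SSEP_L")),
                       window_s = c(0, 0.008), sample_rate = fs,
                       layout = lay),
                  class = "ecap_epochs")
  frames <- temporal_evolution(ep, step_ms = 4)
  expect_length(frames, 2)
  h <- lapply(frames, find_hotspot)
  expect_lte(abs(h[[1]]$angle_deg - 20), 360 / 32)
  expect_lte(abs(h[[2]]$angle_deg - 140), 360 / 32)
  # step = window gives exactly one frame
  expect_length(temporal_evolution(ep, step_ms = 8), 1)
  expect_error(temporal_evolution(ep, step_ms = 10), "step")
})

test_that("hotspot recovery is equivariant under source rotation end to end", {
  spacing <- 360 / 32
  base <- noiseless_config(duration_s = 3, labels = "SSEP_L")
  recover <- function(rot) {
    cfg <- noiseless_config(duration_s = 3, labels = "SSEP_L",
                            rotation_deg = rot)
    s <- simulate_session(cfg)
    den <- denoise_recording(s$recording)
    spikes <- detect_session(den, threshold = 2)
    ep <- epoch(den, s$events, c(0, 0.02))
    map <- peak_amplitudes(ep, spikes)
    find_hotspot(build_topoframe(colMeans(map), s$recording$layout))$angle_deg
  }
  a0 <- recover(0)
  for (rot in c(45, 135, 270)) {
    expect_lte(abs(wrap_angle(recover(rot) - a0 - rot)), spacing)
  }
})
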