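test_that("make_layout spaces electrodes evenly with the midline at zero", {
  lay4 <- make_layout(4)
  expect_setequal(lay4$angles_deg, c(0, 90, -180, -90))
  lay32 <- make_layout(32)
  expect_equal(diff(sort(lay32$angles_deg)), rep(11.25, 31))
  expect_equal(lay32$angles_deg[lay32$midline_index], 0)
  expect_error(make_layout(32, coverage_fraction = 0), "coverage_fraction")
  expect_error(make_layout(1), "n_electrodes")
})

test_that("source gains peak at the hotspot and mirror left/right", {
  lay <- make_layout(32)
  # near-delta bump at the midline
  sharp <- source_profile("SSEP_L", 0, concentration = 5000)
  g <- source_gains(sharp, lay)
  expect_equal(which.max(g), lay$midline_index)
  expect_gt(g[lay$midline_index], 0.999)
  expect_lt(max(g[-lay$midline_index]), 0.01)

  p <- default_source_profiles()
  for (pair in list(c("SSEP_L", "SSEP_R"), c("MEP_L", "MEP_R"))) {
    gl <- source_gains(p[[pair[1]]], lay)
    gr <- source_gains(p[[pair[2]]], lay)
    mirror <- match(wrap_angle(-lay$angles_deg), lay$angles_deg)
    expect_equal(gl, gr[mirror], tolerance = 1e-12)
  }

  # the two-bump MEP profile has exactly two local maxima on the circle
  gfun <- ecaptools:::profile_gain_fun(p$MEP_L)
  th <- seq(-180, 180 - 0.1, by = 0.1)
  v <- gfun(th)
  n <- length(v)
  locmax <- sum(v > v[c(n, 1:(n - 1))] & v >= v[c(2:n, 1)])
  expect_equal(locmax, 2)
})

test_that("noiseless sessions reproduce template amplitude x gain", {
  cfg <- noiseless_config(duration_s = 3, labels = "SSEP_L")
  s <- simulate_session(cfg)
  lay <- s$recording$layout
  g <- source_gains(cfg$profiles$SSEP_L, lay)
  for (e in seq_len(nrow(s$events))) {
    peak_i <- round(s$truth$peak_time_s[e] * cfg$sample_rate) + 1L
    expect_equal(s$recording$data[, peak_i], 50 * g, tolerance = 1e-10)
  }
  expect_equal(s$truth$peak_time_s, s$events$time_s + cfg$latency_s,
               tolerance = 1 / cfg$sample_rate)
})

test_that("the default schedule yields one event per second for 70 s", {
  cfg <- desk_config()
  s <- simulate_session(cfg)
  expect_true(nrow(s$events) %in% c(69, 70))
  expect_equal(diff(s$events$time_s), rep(1, nrow(s$events) - 1))
  expect_equal(nrow(s$truth), nrow(s$events))
})

test_that("the generator is deterministic given a seed", {
  cfg <- desk_config(duration_s = 4)
  a <- simulate_session(cfg, seed = 42)
  b <- simulate_session(cfg, seed = 42)
  expect_identical(a$recording$data, b$recording$data)
  c <- simulate_session(cfg, seed = 43)
  expect_false(identical(a$recording$data, c$recording$data))
})

test_that("event contributions add linearly over a shared noise realization", {
  base <- desk_config(duration_s = 4)
  ev1 <- data.frame(time_s = 1.0, label = "SSEP_L")
  ev2 <- data.frame(time_s = 2.5, label = "MEP_R")
  mk <- function(ev) {
    cfg <- base
    cfg$events <- ev
    simulate_session(cfg, seed = 9)$recording$data
  }
  r1 <- mk(ev1)
  r2 <- mk(ev2)
  r12 <- mk(rbind(ev1, ev2))
  noise <- mk(data.frame(time_s = numeric(0), label = character(0)))
  expect_equal(r12, r1 + r2 - noise, tolerance = 1e-10)
})

test_that("rotating the sources by one electrode spacing permutes the gains", {
  lay <- make_layout(32)
  spacing <- 11.25
  g0 <- source_gains(default_source_profiles(0)$MEP_L, lay)
  g1 <- source_gains(default_source_profiles(spacing)$MEP_L, lay)
  ord <- order(lay$angles_deg)
  v0 <- g0[ord]
  v1 <- g1[ord]
  expect_equal(v1, v0[c(32, 1:31)], tolerance = 1e-4)
})

test_that("noise-only sessions match the configured white-noise SD", {
  cfg <- default_session_config(
    sample_rate = 10000, duration_s = 50, n_electrodes = 2,
    noise = noise_model(ecg_amplitude_uV = 0, resp_amplitude_uV = 0,
                        line_amplitude_uV = 0, white_sigma_uV = 10,
                        stim_artifact_amplitude_uV = 0))
  cfg$events <- data.frame(time_s = numeric(0), label = character(0))
  s <- simulate_session(cfg, seed = 4)
  n <- length(s$recording$data)
  expect_gte(n, 1e6)
  expect_lt(abs(sd(s$recording$data) - 10) / 10, 0.02)
})

test_that("the ECAP template is biphasic with a positive unit peak", {
  w <- ecap_template(30000)
  expect_equal(max(w), 1)
  expect_equal(which.max(w), (length(w) + 1) / 2)
  expect_lt(min(w), 0)
  # near-zero integral relative to the positive lobe mass (the slow
  # counter-phase is truncated at the 4-ms support, so not exactly zero)
  expect_lt(abs(sum(w)) / sum(w[w > 0]), 0.25)
})
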