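test_that("rising-edge triggers fire once per crossing with refractory", {
  fs <- 10000
  expect_length(rising_edge_trigger(rep(1, 1000), fs, 5), 0)
  # step from 0 to twice the threshold: one trigger at the step
  x <- c(rep(0, 99), rep(10, 101))
  trig <- rising_edge_trigger(x, fs, 5)
  expect_equal(trig, 99 / fs)
  # sinusoid crossing the threshold 10 times; oracle crossing count
  t <- seq(0, 1, by = 1 / fs)
  s <- sin(2 * pi * 10 * t)
  trig2 <- rising_edge_trigger(s, fs, threshold_uV = 0.5, refractory_ms = 0)
  g <- s
  oracle <- sum(g[-1] > 0.5 & g[-length(g)] <= 0.5)
  expect_length(trig2, oracle)
  expect_equal(oracle, 10)
  # refractory longer than the period suppresses alternate crossings
  trig3 <- rising_edge_trigger(s, fs, 0.5, refractory_ms = 150)
  expect_length(trig3, 5)
  expect_true(all(diff(trig3) >= 0.150 - 1e-9))
  # gain is applied before the threshold
  expect_length(rising_edge_trigger(0.4 * s, fs, 0.5, gain = 1,
                                    refractory_ms = 0), 0)
  expect_length(rising_edge_trigger(0.4 * s, fs, 0.5, gain = 2,
                                    refractory_ms = 0), 10)
  expect_error(rising_edge_trigger(s, fs, 0), "threshold")
})

test_that("detection latency falls monotonically as the threshold drops", {
  fs <- 10000
  t <- seq(0, 0.01, by = 1 / fs)
  edge <- 50 * exp(-(t - 0.005)^2 / (2 * 0.001^2))   # fixed rising waveform
  lats <- vapply(c(45, 30, 20, 10, 5), function(th)
    rising_edge_trigger(edge, fs, th)[1], numeric(1))
  expect_true(all(diff(lats) < 0))
})

test_that("the bypass recovers conduction latency and shortens it", {
  cfg <- desk_config(duration_s = 20, labels = "MEP_L", seed = 5)
  s <- simulate_session(cfg)
  bp <- simulate_bypass(s, injury_time_s = 10)
  lat <- bp$latencies
  pre <- lat$latency_ms[lat$condition == "pre_injury"]
  post <- lat$latency_ms[lat$condition == "post_bypass"]
  expect_false(anyNA(pre))
  expect_false(anyNA(post))
  # pre-injury latency = conduction (1.5 ms proximal + 1.0 ms distal)
  expect_lte(max(abs(pre - 2.5)), 1000 / cfg$sample_rate + 1e-9)
  # electronic loop beats the natural distal pathway (threshold on the
  # rising edge below the peak)
  expect_lt(mean(post), mean(pre))
  # triggers are ordered and respect the refractory period
  expect_true(all(diff(bp$trigger_times_s) > 0))

  # threshold above every peak: paralysis model, no distal responses
  sc <- default_bypass_scenario()
  sc$threshold_fraction <- 10
  expect_warning(bp2 <- simulate_bypass(s, 10, scenario = sc),
                 "no triggers")
  expect_true(all(is.na(
    bp2$latencies$latency_ms[bp2$latencies$condition == "post_bypass"])))
})

test_that("latency comparisons match closed-form t statistics", {
  x <- c(1.2, 1.4, 1.1, 1.3)
  same <- compare_latencies(x, x, "paired")
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # constant nonzero shift: zero-variance differences are degenerate
  shift <- compare_latencies(c(1, 2, 3), c(2, 3, 4), "paired")
  expect_true(shift$degenerate)
  expect_true(is.na(shift$p))

  set.seed(41)
  for (i in 1:5) {
    pre <- rnorm(8, mean = 2.5, sd = 0.3)
    post <- rnorm(8, mean = 2.2, sd = 0.3)
    pa <- compare_latencies(pre, post, "paired")
    d <- post - pre
    t_oracle <- mean(d) / (sd(d) / sqrt(length(d)))
    p_oracle <- 2 * pt(-abs(t_oracle), length(d) - 1)
    expect_equal(pa$t, t_oracle, tolerance = 1e-10)
    expect_equal(pa$p, p_oracle, tolerance = 1e-10)

    un <- compare_latencies(pre, post, "unpaired")
    se <- sqrt(var(post) / length(post) + var(pre) / length(pre))
    t_w <- (mean(post) - mean(pre)) / se
    df_w <- se^4 / ((var(post) / 8)^2 / 7 + (var(pre) / 8)^2 / 7)
    expect_equal(un$t, t_w, tolerance = 1e-10)
    expect_equal(un$p, 2 * pt(-abs(t_w), df_w), tolerance = 1e-10)
  }
  expect_error(compare_latencies(1, c(1, 2)), ">= 2")
  expect_error(compare_latencies(c(1, 2, 3), c(1, 2), "paired"), "equal")
})
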