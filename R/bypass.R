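#' Rising-edge threshold trigger
#'
#' Emits a trigger at every sample where the amplified signal crosses the
#' threshold from below (`gain * x` moves from `<= threshold` to
#' `> threshold`), then stays silent for the refractory period. This is the
#' computationally minimal detector used for low-latency closed-loop
#' operation.
#'
#' @param x single-channel series (microvolts).
#' @param sample_rate sampling rate in Hz.
#' @param threshold_uV trigger threshold (> 0), applied to the amplified
#'   signal.
#' @param gain pre-threshold amplification factor (default 1).
#' @param refractory_ms post-trigger dead time (default 50 ms).
#' @return Numeric vector of trigger times in seconds (possibly empty).
#' @export
rising_edge_trigger <- function(x, sample_rate, threshold_uV, gain = 1,
                                refractory_ms = 50) {
  if (threshold_uV <= 0) stop("threshold must be > 0")
  if (refractory_ms < 0) stop("refractory must be >= 0")
  g <- gain * x
  n <- length(g)
  if (n < 2L) return(numeric(0))
  crossings <- which(g[-1L] > threshold_uV & g[-n] <= threshold_uV) + 1L
  if (!length(crossings)) return(numeric(0))
  refr <- refractory_ms / 1000 * sample_rate
  keep <- crossings[1L]
  last <- crossings[1L]
  for (i in crossings[-1L]) {
    if (i - last >= refr) {
      keep <- c(keep, i)
      last <- i
    }
  }
  (keep - 1L) / sample_rate
}

#' Default closed-loop bypass scenario
#'
#' A descending (motor) volley peaks at the proximal recording site
#' `latency_s` after the stimulus; the intact distal pathway adds
#' `distal_latency_s` before the muscle response. The electronic loop adds
#' `loop_delay_s` between trigger and distal stimulation, and direct
#' distal stimulation produces a response after `stim_response_latency_s`.
#' The trigger threshold sits on the rising edge at 40% of the expected
#' proximal peak.
#'
#' @param config a [default_session_config()]; MEP-only schedule by
#'   default.
#' @return A list of scenario parameters consumed by [simulate_bypass()].
#' @export
default_bypass_scenario <- function(config = default_session_config(
                                      labels = "MEP_L")) {
  list(config = config,
       distal_latency_s = 0.0010,
       stim_response_latency_s = 0.0010,
       loop_delay_s = 0.0001,
       threshold_fraction = 0.40,
       gain = 10,
       response_amplitude_uV = 200,
       response_noise_uV = 2)
}

#' Simulate the electronic injury bypass
#'
#' Runs the closed loop on a proximal recording: before `injury_time_s`
#' descending events reach the distal segment naturally; after it, the
#' only route is the electronic one — a rising-edge trigger on the
#' proximal hotspot channel issues a distal stimulation command after the
#' loop delay. An EMG-like distal response stream is synthesized and the
#' per-event response latency is measured from it by peak detection.
#'
#' @param session a [simulate_session()] result (proximal recording +
#'   events + truth), typically with an MEP-only schedule.
#' @param injury_time_s time of the simulated cord injury; events before
#'   it are `pre_injury`, events after it `post_bypass`.
#' @param scenario a [default_bypass_scenario()]-style list.
#' @param source_channel proximal channel the trigger listens to; default
#'   the session's modal primary hotspot channel.
#' @param preprocess notch, reference and denoise the proximal recording
#'   before triggering (default TRUE); shared ECG/respiration transients
#'   would otherwise capture the trigger and its refractory period.
#' @param seed seed for the distal response noise.
#' @return A list: `trigger_times_s`, `stim_times_s`, `distal`
#'   ([recording()], 1 channel), `latencies` (data.frame `event_time_s`,
#'   `response_time_s`, `latency_ms`, `condition`), `threshold_uV`,
#'   `source_channel`.
#' @export
simulate_bypass <- function(session, injury_time_s,
                            scenario = default_bypass_scenario(),
                            source_channel = NULL, preprocess = TRUE,
                            seed = 1L) {
  rec <- session$recording
  events <- session$events
  truth <- session$truth
  fs <- rec$sample_rate
  n <- ncol(rec$data)
  if (is.null(source_channel)) {
    tab <- table(truth$primary_channel)
    source_channel <- as.integer(names(tab)[which.max(tab)])
  }
  x <- if (preprocess) preprocess_recording(rec)$data[source_channel, ]
       else rec$data[source_channel, ]
  expected_peak <- median(truth$peak_amplitude_uV)
  threshold_uV <- scenario$threshold_fraction * expected_peak *
    scenario$gain
  refractory_ms <- 500 * min(diff(c(0, events$time_s)))  # half the ISI
  trig <- rising_edge_trigger(x, fs, threshold_uV, gain = scenario$gain,
                              refractory_ms = refractory_ms)
  # triggers matter only once the natural pathway is severed
  trig_post <- trig[trig > injury_time_s]
  stim_times <- trig_post + scenario$loop_delay_s

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  distal <- if (scenario$response_noise_uV > 0)
    rnorm(n, sd = scenario$response_noise_uV) else numeric(n)
  tmpl <- ecap_template(fs) * scenario$response_amplitude_uV
  peak_off <- attr(ecap_template(fs), "peak_offset")
  add_response <- function(stream, peak_time_s) {
    peak_i <- round(peak_time_s * fs)
    idx <- (peak_i - peak_off + 1L):(peak_i - peak_off + length(tmpl))
    keep <- idx >= 1L & idx <= n
    stream[idx[keep]] <- stream[idx[keep]] + tmpl[keep]
    stream
  }
  # natural conduction: proximal peak + distal segment
  nat_lat <- truth$peak_time_s - events$time_s + scenario$distal_latency_s
  for (i in which(events$time_s <= injury_time_s))
    distal <- add_response(distal, events$time_s[i] + nat_lat[i])
  for (ts in stim_times)
    distal <- add_response(distal, ts + scenario$stim_response_latency_s)

  # measure per-event response latency from the distal stream
  win <- round(0.020 * fs)
  resp_time <- rep(NA_real_, nrow(events))
  for (i in seq_len(nrow(events))) {
    i0 <- round(events$time_s[i] * fs) + 1L
    idx <- i0:min(i0 + win, n)
    if (max(distal[idx]) > scenario$response_amplitude_uV / 2)
      resp_time[i] <- (i0 - 1L + which.max(distal[idx]) - 1L) / fs
  }
  condition <- ifelse(events$time_s <= injury_time_s, "pre_injury",
                      "post_bypass")
  lat <- data.frame(event_time_s = events$time_s,
                    response_time_s = resp_time,
                    latency_ms = (resp_time - events$time_s) * 1000,
                    condition = condition)
  if (all(is.na(lat$latency_ms[condition == "post_bypass"])) &&
      any(condition == "post_bypass"))
    warning("no post-injury distal responses: bypass generated no triggers")
  list(trigger_times_s = trig, stim_times_s = stim_times,
       distal = recording(matrix(distal, 1), sample_rate = fs),
       latencies = lat, threshold_uV = threshold_uV,
       source_channel = source_channel)
}

#' Compare pre-injury and post-bypass latencies
#'
#' Two-tailed t test (paired by default) of the response latencies before
#' the injury against those under the electronic bypass, with per-condition
#' means and SDs.
#'
#' @param pre numeric pre-injury latencies (ms).
#' @param post numeric post-bypass latencies (ms).
#' @param variant `"paired"` (default) or `"unpaired"`.
#' @return A list of class `latency_comparison`: `pre_mean`, `pre_sd`,
#'   `post_mean`, `post_sd`, `t`, `p`, `df`, `variant`, `degenerate`.
#'   Identical paired samples give `t = 0, p = 1`; paired differences with
#'   zero variance but nonzero mean are flagged `degenerate` with `p = NA`.
#' @export
compare_latencies <- function(pre, post, variant = c("paired", "unpaired")) {
  variant <- match.arg(variant)
  pre <- pre[!is.na(pre)]; post <- post[!is.na(post)]
  if (length(pre) < 2L || length(post) < 2L)
    stop("need >= 2 latencies per condition")
  if (variant == "paired" && length(pre) != length(post))
    stop("paired comparison needs equal counts")
  out <- list(pre_mean = mean(pre), pre_sd = sd(pre),
              post_mean = mean(post), post_sd = sd(post),
              n_pre = length(pre), n_post = length(post),
              variant = variant, degenerate = FALSE)
  if (variant == "paired") {
    d <- post - pre
    if (sd(d) == 0) {
      if (all(d == 0)) {
        out$t <- 0; out$p <- 1; out$df <- length(d) - 1
      } else {
        out$t <- NA_real_; out$p <- NA_real_; out$df <- length(d) - 1
        out$degenerate <- TRUE
      }
      class(out) <- "latency_comparison"
      return(out)
    }
    tt <- t.test(post, pre, paired = TRUE)
  } else {
    if (sd(pre) == 0 && sd(post) == 0) {
      if (mean(pre) == mean(post)) {
        out$t <- 0; out$p <- 1; out$df <- length(pre) + length(post) - 2
      } else {
        out$t <- NA_real_; out$p <- NA_real_
        out$df <- length(pre) + length(post) - 2
        out$degenerate <- TRUE
      }
      class(out) <- "latency_comparison"
      return(out)
    }
    tt <- t.test(post, pre, var.equal = FALSE)
  }
  out$t <- unname(tt$statistic)
  out$p <- tt$p.value
  out$df <- unname(tt$parameter)
  class(out) <- "latency_comparison"
  out
}

#' @export
print.latency_comparison <- function(x, ...) {
  cat(sprintf("<latency_comparison> (%s) pre %.4f +/- %.4f ms, post %.4f +/- %.4f ms\n",
              x$variant, x$pre_mean, x$pre_sd, x$post_mean, x$post_sd))
  cat(sprintf("t = %.4f, two-tailed p = %.4g\n", x$t, x$p))
  invisible(x)
}
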