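#' Build an evenly spaced circumferential layout
#'
#' Electrodes are spread uniformly over `coverage_fraction` of the full
#' circle, spacing `360 * coverage_fraction / n_electrodes` degrees, centred
#' so that one electrode sits exactly on the dorsal midline (0 degrees).
#'
#' @param n_electrodes number of electrodes (>= 2, default 32).
#' @param coverage_fraction fraction of the circumference covered, (0, 1].
#' @param device_length_mm device length, one of 8.90, 9.90, 10.90.
#' @return An [electrode_layout()].
#' @examples
#' make_layout(32)$angles_deg   # spacing 11.25 degrees
#' @export
make_layout <- function(n_electrodes = 32, coverage_fraction = 1.0,
                        device_length_mm = 9.90) {
  if (!is.numeric(n_electrodes) || length(n_electrodes) != 1L ||
      n_electrodes < 2 || n_electrodes != round(n_electrodes))
    stop("n_electrodes must be an integer >= 2")
  if (!is.numeric(coverage_fraction) || length(coverage_fraction) != 1L ||
      coverage_fraction <= 0 || coverage_fraction > 1)
    stop("coverage_fraction must lie in (0, 1]")
  spacing <- 360 * coverage_fraction / n_electrodes
  midline <- floor(n_electrodes / 2) + 1L
  angles <- spacing * (seq_len(n_electrodes) - midline)
  angles <- wrap_angle(angles)
  electrode_layout(angles, device_length_mm = device_length_mm,
                   coverage_fraction = coverage_fraction)
}

#' Wrap angles to [-180, 180)
#' @param x angles in degrees.
#' @return Wrapped angles.
#' @export
wrap_angle <- function(x) ((x + 180) %% 360) - 180

#' Angular source profile of an evoked-potential source
#'
#' A source is a mixture of von Mises-shaped hotspot bumps on the circle,
#' `g(theta) = sum_b a_b * exp(kappa_b * (cos(theta - theta_b) - 1))`,
#' normalized so the maximum over the circle is 1. Somatosensory sources
#' (SSEP, tibial, peroneal) have a single dorsal, side-shifted hotspot;
#' motor sources (MEP) have a lateral + ventrolateral pair. Left/right
#' profiles of the same modality are mirror images through the dorsal
#' midline.
#'
#' @param label source label, one of [SOURCE_LABELS].
#' @param hotspot_angles_deg hotspot centre(s) in degrees.
#' @param concentration von Mises concentration kappa per bump (recycled).
#' @param relative_amplitudes per-bump scale (recycled), max-normalized
#'   later.
#' @return An object of class `source_profile`.
#' @export
source_profile <- function(label, hotspot_angles_deg, concentration = 8,
                           relative_amplitudes = 1) {
  if (!label %in% SOURCE_LABELS) stop("unknown label: ", label)
  nb <- length(hotspot_angles_deg)
  structure(
    list(label = label,
         hotspot_angles_deg = wrap_angle(as.numeric(hotspot_angles_deg)),
         concentration = rep_len(concentration, nb),
         relative_amplitudes = rep_len(relative_amplitudes, nb)),
    class = "source_profile")
}

#' Default angular profiles for the six source labels
#'
#' SSEP_L/R: single hotspot at +/-25 degrees (dorsal column, side-shifted),
#' kappa 8. MEP_L/R: lateral (+/-90) and ventrolateral (+/-140) hotspots,
#' kappa 12, relative amplitudes 0.8/1.0. TIBIAL (+15) and PERONEAL (+45)
#' are dorsal SSEP sub-sources. `rotation_deg` rotates every hotspot, which
#' rotation-equivariance tests exploit.
#'
#' @param rotation_deg rigid rotation applied to all hotspot angles.
#' @return Named list of [source_profile()] objects.
#' @export
default_source_profiles <- function(rotation_deg = 0) {
  p <- list(
    SSEP_L = source_profile("SSEP_L", 25, 8),
    SSEP_R = source_profile("SSEP_R", -25, 8),
    MEP_L = source_profile("MEP_L", c(90, 140), 12, c(0.8, 1.0)),
    MEP_R = source_profile("MEP_R", c(-90, -140), 12, c(0.8, 1.0)),
    TIBIAL = source_profile("TIBIAL", 15, 8),
    PERONEAL = source_profile("PERONEAL", 45, 8))
  if (rotation_deg != 0) {
    p <- lapply(p, function(sp) {
      sp$hotspot_angles_deg <- wrap_angle(sp$hotspot_angles_deg + rotation_deg)
      sp
    })
  }
  p
}

profile_gain_fun <- function(profile) {
  th0 <- profile$hotspot_angles_deg * pi / 180
  kap <- profile$concentration
  amp <- profile$relative_amplitudes
  # normalize the bump mixture to max 1 on a dense circular grid
  grid <- seq(-pi, pi, length.out = 4096L)
  mix <- function(th) {
    g <- 0
    for (b in seq_along(th0))
      g <- g + amp[b] * exp(kap[b] * (cos(th - th0[b]) - 1))
    g
  }
  peak <- max(mix(grid))
  function(theta_deg) mix(theta_deg * pi / 180) / peak
}

#' Per-channel gains of a source on a layout
#'
#' Evaluates the profile's normalized hotspot mixture at each electrode
#' angle. Gains lie in \[0, 1\]; the argmax channel is the electrode nearest
#' a hotspot centre.
#'
#' @param profile a [source_profile()].
#' @param layout an [electrode_layout()].
#' @return Numeric gain vector, one entry per electrode.
#' @export
source_gains <- function(profile, layout) {
  stopifnot(inherits(profile, "source_profile"),
            inherits(layout, "electrode_layout"))
  profile_gain_fun(profile)(layout$angles_deg)
}

#' Biphasic ECAP waveform template
#'
#' Difference-of-Gaussians pulse with a dominant positive phase: a narrow
#' positive Gaussian minus a broad one scaled so the (untruncated) integral
#' is zero, sampled over the `duration_ms` support and normalized to peak 1
#' at the centre sample.
#'
#' @param sample_rate sampling rate in Hz.
#' @param duration_ms total support (default 4 ms, the analysis window).
#' @param sigma1_ms width of the positive phase (default 0.4 ms).
#' @param sigma2_ms width of the slow counter-phase (default 1.2 ms).
#' @return Numeric waveform vector of length `round(duration_ms/1000 *
#'   sample_rate)` (forced odd so the peak is the centre sample), with
#'   attribute `peak_offset` (0-based index of the peak).
#' @export
ecap_template <- function(sample_rate, duration_ms = 4, sigma1_ms = 0.4,
                          sigma2_ms = 1.2) {
  n <- round(duration_ms / 1000 * sample_rate)
  if (n %% 2 == 0) n <- n + 1L
  t <- (seq_len(n) - (n + 1) / 2) / sample_rate
  s1 <- sigma1_ms / 1000
  s2 <- sigma2_ms / 1000
  w <- exp(-t^2 / (2 * s1^2)) - (s1 / s2) * exp(-t^2 / (2 * s2^2))
  w <- w / max(w)
  attr(w, "peak_offset") <- (n - 1L) / 2
  w
}

#' Ricker (Mexican-hat) wavelet
#'
#' `(1 - (t/a)^2) * exp(-t^2 / (2 a^2))`, zero crossings at `t = +/- a`, so
#' the central lobe is `2a` wide. Used both as the synthetic QRS-like
#' cardiac transient and as the analysis kernel of [extract_cardiac()].
#'
#' @param t_s times in seconds (0 at the pulse centre).
#' @param a_s scale parameter in seconds (half the central-lobe width).
#' @return Wavelet values at `t_s`.
#' @export
ricker_wavelet <- function(t_s, a_s) {
  (1 - (t_s / a_s)^2) * exp(-t_s^2 / (2 * a_s^2))
}

#' Noise and artifact model for the generator
#'
#' All amplitudes are in microvolts; setting every amplitude to 0 yields a
#' noiseless recording. The ECG transient is a shared Ricker-shaped pulse
#' train (rat heart rate 6 Hz) with per-channel gains; respiration and
#' 50-Hz mains are shared sinusoids; white instrument noise is independent
#' per channel; the stimulation artifact is a brief shared biphasic
#' transient at each event time.
#'
#' @param ecg_rate_hz heart rate (default 6).
#' @param ecg_amplitude_uV QRS-like transient peak (default 30).
#' @param ecg_width_ms central-lobe width of the transient (default 5).
#' @param ecg_channel_gains per-channel ECG gain (default all 1 = common).
#' @param resp_rate_hz respiration rate (default 1).
#' @param resp_amplitude_uV respiration drift amplitude (default 20).
#' @param line_freq_hz mains frequency (default 50).
#' @param line_amplitude_uV mains amplitude (default 10).
#' @param white_sigma_uV white-noise SD (default 10).
#' @param stim_artifact_amplitude_uV stimulation artifact peak (default 100).
#' @param stim_artifact_duration_ms stimulation artifact length (default 0.5).
#' @return A named list of class `noise_model`.
#' @export
noise_model <- function(ecg_rate_hz = 6, ecg_amplitude_uV = 30,
                        ecg_width_ms = 5, ecg_channel_gains = NULL,
                        resp_rate_hz = 1, resp_amplitude_uV = 20,
                        line_freq_hz = 50, line_amplitude_uV = 10,
                        white_sigma_uV = 10,
                        stim_artifact_amplitude_uV = 100,
                        stim_artifact_duration_ms = 0.5) {
  amps <- c(ecg_amplitude_uV, resp_amplitude_uV, line_amplitude_uV,
            white_sigma_uV, stim_artifact_amplitude_uV)
  if (any(amps < 0)) stop("noise amplitudes must be >= 0")
  structure(
    list(ecg_rate_hz = ecg_rate_hz, ecg_amplitude_uV = ecg_amplitude_uV,
         ecg_width_ms = ecg_width_ms, ecg_channel_gains = ecg_channel_gains,
         resp_rate_hz = resp_rate_hz, resp_amplitude_uV = resp_amplitude_uV,
         line_freq_hz = line_freq_hz, line_amplitude_uV = line_amplitude_uV,
         white_sigma_uV = white_sigma_uV,
         stim_artifact_amplitude_uV = stim_artifact_amplitude_uV,
         stim_artifact_duration_ms = stim_artifact_duration_ms),
    class = "noise_model")
}

#' Default session configuration
#'
#' The conditions of the reference acquisition protocol: a 70-s session of
#' alternating left/right MEP/SSEP stimulation at a 1-s inter-stimulus
#' interval (first event at 0.5 s, 70 events), recorded on a 32-electrode
#' full-coverage circumferential layout at 30 kHz. ECAPs peak 1.5 ms after
#' the stimulus with hotspot amplitude 50 uV over a 10-uV white-noise floor
#' (peak SNR 5). See the methods vignette for how each value was chosen.
#'
#' @param sample_rate sampling rate in Hz; analyses at desk scale may pass
#'   a reduced rate such as 10000.
#' @param duration_s session length in seconds.
#' @param isi_s inter-stimulus interval in seconds.
#' @param first_event_s time of the first stimulus.
#' @param labels label cycle for the alternating schedule.
#' @param amplitude_uV ECAP amplitude at the hotspot.
#' @param latency_s conduction delay from stimulus to ECAP peak.
#' @param stim_amplitude_uA nominal stimulation amplitude (metadata).
#' @param n_electrodes,coverage_fraction layout parameters.
#' @param rotation_deg rigid rotation applied to all source hotspots.
#' @param noise a [noise_model()].
#' @param profiles named list of [source_profile()]s (defaults rotated by
#'   `rotation_deg`).
#' @param seed global random seed for the generator.
#' @return A nested configuration list of class `session_config`.
#' @export
default_session_config <- function(sample_rate = 30000, duration_s = 70,
                                   isi_s = 1, first_event_s = 0.5,
                                   labels = c("MEP_L", "SSEP_L", "MEP_R",
                                              "SSEP_R"),
                                   amplitude_uV = 50, latency_s = 0.0015,
                                   stim_amplitude_uA = 100,
                                   n_electrodes = 32, coverage_fraction = 1,
                                   rotation_deg = 0,
                                   noise = noise_model(),
                                   profiles = NULL, seed = 1L) {
  if (is.null(profiles)) profiles <- default_source_profiles(rotation_deg)
  structure(
    list(sample_rate = sample_rate, duration_s = duration_s, isi_s = isi_s,
         first_event_s = first_event_s, labels = labels,
         amplitude_uV = amplitude_uV, latency_s = latency_s,
         stim_amplitude_uA = stim_amplitude_uA, n_electrodes = n_electrodes,
         coverage_fraction = coverage_fraction, noise = noise,
         profiles = profiles, events = NULL, seed = seed),
    class = "session_config")
}

# event schedule implied by a config (config$events overrides)
schedule_events <- function(config) {
  if (!is.null(config$events)) {
    ev <- config$events
    return(event_table(ev$time_s, ev$label,
                       if (is.null(ev$stim_amplitude_uA)) config$stim_amplitude_uA
                       else ev$stim_amplitude_uA))
  }
  # keep the full analysis window inside the recording
  margin <- 0.025
  if (config$first_event_s > config$duration_s - margin)
    stop("event schedule longer than recording duration")
  times <- seq(config$first_event_s, config$duration_s - margin,
               by = config$isi_s)
  labels <- rep_len(config$labels, length(times))
  event_table(times, labels, config$stim_amplitude_uA)
}

#' Simulate a circumferential recording session
#'
#' Builds the clean signal as the sum over events of the ECAP template,
#' delayed by the conduction latency and scaled per channel by the source's
#' angular gains, then adds (in order) the ECG train, respiration drift,
#' mains interference, white noise, and stimulation artifacts. Noise is
#' drawn before and independently of the event schedule, so two sessions
#' sharing a seed share a noise realization regardless of their events.
#'
#' @param config a [default_session_config()]-style list.
#' @param seed random seed; defaults to `config$seed`.
#' @return A list with elements `recording` ([recording()]), `events`
#'   ([event_table()]), and `truth`: a data.frame with one row per event
#'   (`time_s`, `label`, `peak_time_s`, `primary_channel`,
#'   `primary_angle_deg`, `peak_amplitude_uV`) carrying the clean
#'   events x channels peak-amplitude matrix as attribute
#'   `clean_amplitudes` and the layout as attribute `layout`.
#' @export
simulate_session <- function(config, seed = config$seed) {
  fs <- config$sample_rate
  n <- round(config$duration_s * fs)
  layout <- make_layout(config$n_electrodes, config$coverage_fraction)
  nch <- layout$n_electrodes
  events <- schedule_events(config)
  if (nrow(events) && max(events$time_s) >= config$duration_s)
    stop("event schedule longer than recording duration")
  nm <- config$noise

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)

  ## --- noise, drawn independently of the schedule ---------------------
  phases <- runif(3, 0, 2 * pi)
  data <- matrix(0, nch, n)
  tvec <- (seq_len(n) - 1L) / fs
  if (nm$ecg_amplitude_uV > 0) {
    a_s <- nm$ecg_width_ms / 2000       # half central-lobe width, seconds
    beat_period <- 1 / nm$ecg_rate_hz
    first_beat <- phases[1] / (2 * pi) * beat_period
    beats <- seq(first_beat, config$duration_s, by = beat_period)
    ecg <- numeric(n)
    half <- round(3 * a_s * fs)
    kern <- nm$ecg_amplitude_uV *
      ricker_wavelet((-half:half) / fs, a_s)
    for (b in beats) {
      c0 <- round(b * fs)
      idx <- (c0 - half):(c0 + half) + 1L
      keep <- idx >= 1L & idx <= n
      ecg[idx[keep]] <- ecg[idx[keep]] + kern[keep]
    }
    gains <- if (is.null(nm$ecg_channel_gains)) rep(1, nch)
             else rep_len(nm$ecg_channel_gains, nch)
    data <- data + gains %o% ecg
  }
  if (nm$resp_amplitude_uV > 0) {
    resp <- nm$resp_amplitude_uV *
      sin(2 * pi * nm$resp_rate_hz * tvec + phases[2])
    data <- data + rep(1, nch) %o% resp
  }
  if (nm$line_amplitude_uV > 0) {
    line <- nm$line_amplitude_uV *
      sin(2 * pi * nm$line_freq_hz * tvec + phases[3])
    data <- data + rep(1, nch) %o% line
  }
  if (nm$white_sigma_uV > 0)
    data <- data + matrix(rnorm(nch * n, sd = nm$white_sigma_uV), nch, n)
  if (nm$stim_artifact_amplitude_uV > 0) {
    dur <- round(nm$stim_artifact_duration_ms / 1000 * fs)
    if (dur >= 2) {
      art <- nm$stim_artifact_amplitude_uV *
        sin(2 * pi * seq(0, 1, length.out = dur))
      for (te in events$time_s) {
        i0 <- round(te * fs) + 1L
        idx <- i0:(i0 + dur - 1L)
        keep <- idx <= n
        data[, idx[keep]] <- data[, idx[keep]] +
          rep(1, nch) %o% art[keep]
      }
    }
  }

  ## --- clean evoked responses ----------------------------------------
  tmpl <- ecap_template(fs)
  peak_off <- attr(tmpl, "peak_offset")
  ntw <- length(tmpl)
  clean_amp <- matrix(0, nrow(events), nch)
  peak_times <- numeric(nrow(events))
  primary_channel <- integer(nrow(events))
  primary_angle <- numeric(nrow(events))
  gain_cache <- lapply(config$profiles, source_gains, layout = layout)
  for (e in seq_len(nrow(events))) {
    lbl <- events$label[e]
    g <- gain_cache[[lbl]]
    if (is.null(g)) stop("no source profile for label ", lbl)
    peak_i <- round((events$time_s[e] + config$latency_s) * fs)  # 0-based
    start <- peak_i - peak_off + 1L                              # 1-based
    idx <- start:(start + ntw - 1L)
    keep <- idx >= 1L & idx <= n
    amp <- config$amplitude_uV
    data[, idx[keep]] <- data[, idx[keep]] + (amp * g) %o% tmpl[keep]
    clean_amp[e, ] <- amp * g
    peak_times[e] <- peak_i / fs
    primary_channel[e] <- which.max(g)
    prof <- config$profiles[[lbl]]
    primary_angle[e] <-
      prof$hotspot_angles_deg[which.max(prof$relative_amplitudes)]
  }

  rec <- recording(data, sample_rate = fs, layout = layout,
                   annotations = list(generator = "ecaptools-synth",
                                      seed = seed))
  truth <- data.frame(time_s = events$time_s, label = events$label,
                      peak_time_s = peak_times,
                      primary_channel = primary_channel,
                      primary_angle_deg = primary_angle,
                      peak_amplitude_uV = clean_amp[cbind(seq_len(nrow(events)),
                                                          primary_channel)])
  attr(truth, "clean_amplitudes") <- clean_amp
  attr(truth, "layout") <- layout
  list(recording = rec, events = events, truth = truth)
}
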