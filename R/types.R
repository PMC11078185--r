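#' Electrode layout around the cord circumference
#'
#' Describes where each electrode of a circumferential array sits, as an
#' angle around the cord. The angle convention used throughout the package
#' is: 0 degrees at the dorsal midline, increasing toward the animal's left
#' (viewed from rostral), so +90 is left lateral, -90 right lateral and
#' +/-180 the ventral midline. Angles live in [-180, 180).
#'
#' @param angles_deg numeric vector of per-electrode angles in degrees,
#'   strictly ordered along the device, containing exactly one electrode at
#'   0 degrees (the dorsal-midline calibration electrode).
#' @param device_length_mm physical device length; one of 8.90, 9.90, 10.90.
#' @param coverage_fraction fraction of the circumference covered, in (0, 1].
#'
#' @return An object of class `electrode_layout` with fields
#'   `n_electrodes`, `angles_deg`, `midline_index`, `device_length_mm`,
#'   `coverage_fraction`.
#' @seealso [make_layout()] for the evenly-spaced constructor.
#' @export
electrode_layout <- function(angles_deg, device_length_mm = 9.90,
                             coverage_fraction = 1.0) {
  angles_deg <- as.numeric(angles_deg)
  if (length(angles_deg) < 2L)
    stop("an electrode layout needs at least 2 electrodes")
  if (anyNA(angles_deg) || any(angles_deg < -180 | angles_deg >= 180))
    stop("angles_deg must lie in [-180, 180)")
  if (any(diff(angles_deg) <= 0) && any(diff(rev(angles_deg)) <= 0))
    stop("angles_deg must be strictly ordered along the device")
  midline <- which(angles_deg == 0)
  if (length(midline) != 1L)
    stop("exactly one electrode must sit at the dorsal midline (0 degrees)")
  if (!is.numeric(coverage_fraction) || length(coverage_fraction) != 1L ||
      coverage_fraction <= 0 || coverage_fraction > 1)
    stop("coverage_fraction must lie in (0, 1]")
  if (!device_length_mm %in% c(8.90, 9.90, 10.90))
    stop("device_length_mm must be one of 8.90, 9.90, 10.90")
  structure(
    list(n_electrodes = length(angles_deg),
         angles_deg = angles_deg,
         midline_index = midline,
         device_length_mm = device_length_mm,
         coverage_fraction = coverage_fraction),
    class = "electrode_layout")
}

#' @export
print.electrode_layout <- function(x, ...) {
  cat(sprintf(
    "<electrode_layout> %d electrodes, %.0f%% coverage, %.2f mm device\n",
    x$n_electrodes, 100 * x$coverage_fraction, x$device_length_mm))
  invisible(x)
}

#' Multichannel epidural recording
#'
#' Container for a channels x samples matrix of epidural potentials in
#' microvolts, sampled at a fixed rate, with an optional electrode layout.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param sample_rate sampling rate in Hz (acquisition default 30000).
#' @param channel_ids optional character vector of channel identifiers.
#' @param layout optional [electrode_layout()]; when given, its electrode
#'   count must equal the channel count.
#' @param annotations free-form named list of metadata.
#'
#' @return An object of class `ecap_recording`.
#' @export
recording <- function(data, sample_rate = 30000, channel_ids = NULL,
                      layout = NULL, annotations = list()) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("data must be a numeric channels x samples matrix")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L ||
      !is.finite(sample_rate) || sample_rate <= 0)
    stop("sample_rate must be a single positive number")
  nch <- nrow(data)
  if (is.null(channel_ids)) channel_ids <- sprintf("ch%02d", seq_len(nch))
  if (length(channel_ids) != nch)
    stop("channel_ids length must equal the channel count")
  if (!is.null(layout)) {
    if (!inherits(layout, "electrode_layout"))
      stop("layout must be an electrode_layout")
    if (layout$n_electrodes != nch)
      stop(sprintf(
        "channel/layout mismatch: %d channels but %d layout electrodes",
        nch, layout$n_electrodes))
  }
  structure(
    list(data = data, sample_rate = sample_rate, channel_ids = channel_ids,
         layout = layout, annotations = annotations),
    class = "ecap_recording")
}

#' @export
print.ecap_recording <- function(x, ...) {
  cat(sprintf("<ecap_recording> %d channels x %d samples @ %g Hz (%.2f s)\n",
              nrow(x$data), ncol(x$data), x$sample_rate,
              ncol(x$data) / x$sample_rate))
  if (!is.null(x$layout)) print(x$layout)
  invisible(x)
}

#' Recording duration in seconds
#' @param rec an [recording()] object.
#' @return Duration in seconds.
#' @export
duration_s <- function(rec) {
  stopifnot(inherits(rec, "ecap_recording"))
  ncol(rec$data) / rec$sample_rate
}

#' Recognised evoked-potential source labels
#'
#' Left/right motor evoked potentials (MEP), left/right somatosensory
#' evoked potentials (SSEP), and the tibial/peroneal SSEP sub-sources.
#' @export
SOURCE_LABELS <- c("MEP_L", "MEP_R", "SSEP_L", "SSEP_R", "TIBIAL", "PERONEAL")

#' Stimulation event table
#'
#' @param time_s event times in seconds from recording start, strictly
#'   increasing.
#' @param label source labels, each one of [SOURCE_LABELS].
#' @param stim_amplitude_uA stimulation amplitudes in microamperes.
#'
#' @return A `data.frame` of class `event_table` with columns `time_s`,
#'   `label`, `stim_amplitude_uA`.
#' @export
event_table <- function(time_s, label, stim_amplitude_uA = NA_real_) {
  time_s <- as.numeric(time_s)
  label <- as.character(label)
  if (length(time_s) != length(label))
    stop("time_s and label must have the same length")
  bad <- setdiff(unique(label), SOURCE_LABELS)
  if (length(bad))
    stop("unknown label(s): ", paste(bad, collapse = ", "))
  if (length(time_s) > 1L && any(diff(time_s) <= 0))
    stop("event times must be strictly increasing")
  out <- data.frame(time_s = time_s, label = label,
                    stim_amplitude_uA = rep_len(as.numeric(stim_amplitude_uA),
                                                length(time_s)))
  class(out) <- c("event_table", "data.frame")
  out
}
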