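#' Channels on the ventral arc of a layout
#'
#' With the default source profiles no evoked source projects near the
#' ventral midline, so ventral electrodes are natural "dormant" reference
#' candidates.
#'
#' @param layout an [electrode_layout()].
#' @param min_abs_angle_deg channels with `|angle| >=` this are returned
#'   (default 160).
#' @return Integer channel indices.
#' @export
ventral_channels <- function(layout, min_abs_angle_deg = 160) {
  which(abs(layout$angles_deg) >= min_abs_angle_deg |
          layout$angles_deg <= -min_abs_angle_deg)
}

#' Denoise every channel of a recording
#'
#' Applies [denoise()] channel by channel.
#'
#' @param rec an [recording()].
#' @param levels,variant passed to [denoise()].
#' @return The denoised [recording()].
#' @export
denoise_recording <- function(rec, levels = 3, variant = "stationary") {
  stopifnot(inherits(rec, "ecap_recording"))
  out <- rec
  for (ch in seq_len(nrow(rec$data)))
    out$data[ch, ] <- denoise(rec$data[ch, ], levels = levels,
                              variant = variant)
  out$annotations$denoised <- list(levels = levels, variant = variant)
  out
}

#' Standard preprocessing chain
#'
#' 50-Hz notch, referencing of active channels to the dormant set, then
#' per-channel wavelet denoising.
#'
#' @param rec an [recording()].
#' @param dormant dormant channel indices; default [ventral_channels()] of
#'   the recording's layout.
#' @param notch apply the 50-Hz notch (default TRUE).
#' @return The processed [recording()].
#' @export
preprocess_recording <- function(rec, dormant = NULL, notch = TRUE) {
  stopifnot(inherits(rec, "ecap_recording"))
  if (is.null(dormant)) {
    if (is.null(rec$layout))
      stop("dormant channels must be given when the recording has no layout")
    dormant <- ventral_channels(rec$layout)
  }
  if (notch) rec <- notch_filter(rec)
  rec <- reference_channels(rec, dormant)
  denoise_recording(rec)
}

#' Detect spikes on every channel
#'
#' Runs [detect_spikes()] per channel of a (denoised) recording and stacks
#' the results.
#'
#' @param rec a denoised [recording()].
#' @param channels channels to scan (default all). Reference (dormant)
#'   channels should be excluded: they are passed through referencing
#'   unchanged and still carry the shared artifacts.
#' @param threshold fixed detection threshold for every channel; default
#'   NULL computes each channel's own [detection_threshold()].
#' @param ... passed to [detect_spikes()].
#' @return data.frame with columns `channel`, `peak_index`, `peak_time_s`,
#'   `peak_amplitude_uV`, `edge`, `threshold_uV`.
#' @export
detect_session <- function(rec, channels = seq_len(nrow(rec$data)),
                           threshold = NULL, ...) {
  stopifnot(inherits(rec, "ecap_recording"))
  res <- lapply(channels, function(ch) {
    x <- rec$data[ch, ]
    th <- if (is.null(threshold)) detection_threshold(x) else threshold
    det <- detect_spikes(x, rec$sample_rate, threshold = th, ...)
    if (!nrow(det$spikes)) return(NULL)
    cbind(channel = ch, det$spikes, threshold_uV = th)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res))
    return(data.frame(channel = integer(0), peak_index = integer(0),
                      peak_time_s = numeric(0),
                      peak_amplitude_uV = numeric(0), edge = logical(0),
                      threshold_uV = numeric(0)))
  do.call(rbind, res)
}

#' Detection performance against generator ground truth
#'
#' Sensitivity: fraction of events with a detection on the event's primary
#' hotspot channel within `tol_ms` of the true peak time. False-discovery
#' rate: fraction of all detections (any channel) not attributable to any
#' event within `tol_ms`. Peak-time error: mean absolute error, in
#' samples, of the matched primary-channel detections.
#'
#' @param spikes a [detect_session()] data.frame.
#' @param truth the `truth` element of [simulate_session()].
#' @param sample_rate sampling rate in Hz.
#' @param tol_ms attribution window (default 1 ms).
#' @return One-row data.frame: `sensitivity`, `fdr`,
#'   `peak_time_mae_samples`, `n_events`, `n_detections`.
#' @export
detection_metrics <- function(spikes, truth, sample_rate, tol_ms = 1) {
  tol <- tol_ms / 1000
  nev <- nrow(truth)
  hit <- logical(nev)
  err <- rep(NA_real_, nev)
  for (e in seq_len(nev)) {
    on_primary <- spikes$channel == truth$primary_channel[e]
    dt <- abs(spikes$peak_time_s[on_primary] - truth$peak_time_s[e])
    if (length(dt) && min(dt) <= tol) {
      hit[e] <- TRUE
      err[e] <- min(dt) * sample_rate
    }
  }
  false_det <- if (nrow(spikes)) {
    vapply(spikes$peak_time_s, function(t)
      min(abs(t - truth$peak_time_s)) > tol, logical(1))
  } else logical(0)
  data.frame(sensitivity = mean(hit),
             fdr = if (nrow(spikes)) mean(false_det) else 0,
             peak_time_mae_samples = mean(err[hit]),
             n_events = nev, n_detections = nrow(spikes))
}

#' Full session feature extraction
#'
#' Preprocess, detect, epoch, and assemble the per-event peak-amplitude
#' map with its labels — the input of classification.
#'
#' @param session a [simulate_session()] result (or an equivalent list
#'   with `recording` and `events`).
#' @param window_s epoch window (default 0 to +20 ms).
#' @param dormant,notch passed to [preprocess_recording()].
#' @return List: `map` ([peak_amplitudes()] matrix), `labels`, `epochs`,
#'   `spikes`, `processed` (the denoised recording).
#' @export
session_features <- function(session, window_s = c(0, 0.02),
                             dormant = NULL, notch = TRUE) {
  if (is.null(dormant) && !is.null(session$recording$layout))
    dormant <- ventral_channels(session$recording$layout)
  proc <- preprocess_recording(session$recording, dormant = dormant,
                               notch = notch)
  active <- setdiff(seq_len(nrow(proc$data)), dormant)
  spikes <- detect_session(proc, channels = active)
  ep <- epoch(proc, session$events, window_s)
  map <- peak_amplitudes(ep, spikes)
  list(map = map, labels = ep$events$label, epochs = ep, spikes = spikes,
       processed = proc)
}

#' Classify a session's evoked-potential sources
#'
#' Binarized peak-amplitude features, stratified 60/40 split, and
#' city-block KNN with `k = 1`.
#'
#' @param map events x channels peak-amplitude matrix.
#' @param labels per-event source labels.
#' @param train_fraction,seed,k see [split_stratified()] / [knn_classify()].
#' @return The [knn_classify()] result, with the split attached as
#'   attribute `split`.
#' @export
classify_session <- function(map, labels, train_fraction = 0.60, seed = 1L,
                             k = 1) {
  feat <- binarize(map)
  sp <- split_stratified(labels, train_fraction, seed)
  res <- knn_classify(feat[sp$train, , drop = FALSE], labels[sp$train],
                      feat[sp$test, , drop = FALSE], k = k,
                      test_y = labels[sp$test])
  attr(res, "split") <- sp
  res
}
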