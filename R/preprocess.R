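#' Reference active channels to dormant counterparts
#'
#' Subtracts a reference signal, built from channels that carry no evoked
#' response ("dormant" channels), from every active channel. This removes
#' artifact sources shared across the array (ECG, respiration, stimulation
#' and movement transients). Dormant channels are passed through unchanged.
#'
#' @param rec an [recording()].
#' @param dormant integer indices of the dormant channel set (non-empty).
#' @param scheme `"mean"` (default): reference is the mean of the dormant
#'   set; `"single"`: each active channel is referenced to the first
#'   dormant channel.
#' @return A referenced [recording()] of the same shape.
#' @export
reference_channels <- function(rec, dormant, scheme = c("mean", "single")) {
  stopifnot(inherits(rec, "ecap_recording"))
  scheme <- match.arg(scheme)
  nch <- nrow(rec$data)
  if (length(dormant) == 0L) stop("dormant channel set must not be empty")
  dormant <- as.integer(dormant)
  if (any(dormant < 1L | dormant > nch))
    stop("dormant channel index out of range")
  active <- setdiff(seq_len(nch), dormant)
  ref <- if (scheme == "mean" && length(dormant) > 1L)
    colMeans(rec$data[dormant, , drop = FALSE])
  else rec$data[dormant[1L], ]
  out <- rec
  out$data[active, ] <- rec$data[active, , drop = FALSE] -
    rep(1, length(active)) %o% ref
  out$annotations$reference <- list(scheme = scheme, dormant = dormant)
  out
}

#' Zero-phase notch filter
#'
#' Second-order IIR notch (constrained biquad), applied forward and
#' backward with [signal::filtfilt()] so that evoked-potential latencies
#' are not shifted.
#'
#' @param rec an [recording()].
#' @param freq_hz notch centre frequency (default 50, mains).
#' @param q quality factor; bandwidth is `freq_hz / q` (default 30).
#' @return The filtered [recording()].
#' @export
notch_filter <- function(rec, freq_hz = 50, q = 30) {
  stopifnot(inherits(rec, "ecap_recording"))
  fs <- rec$sample_rate
  if (freq_hz <= 0 || freq_hz >= fs / 2)
    stop("notch frequency must lie strictly below the Nyquist frequency")
  w0 <- 2 * pi * freq_hz / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  out <- rec
  for (ch in seq_len(nrow(rec$data)))
    out$data[ch, ] <- signal::filtfilt(b, a, rec$data[ch, ])
  out$annotations$notch <- list(freq_hz = freq_hz, q = q)
  out
}

#' Extract event-locked epochs
#'
#' Cuts one window per stimulation event, covering `[t - pre, t + post)`
#' seconds around each event time. The sample at the event time is window
#' index `floor(pre * sample_rate)` (0-based). Events whose window falls
#' partly outside the recording are dropped with a warning.
#'
#' @param rec an [recording()].
#' @param events an [event_table()].
#' @param window_s numeric `(pre, post)` in seconds, both >= 0, summing to
#'   a positive window length. Default `c(0, 0.02)`: 0 to +20 ms.
#' @return An object of class `ecap_epochs`: list with `data` (events x
#'   channels x samples array), `events` (the retained rows), `window_s`,
#'   `sample_rate`, `layout`.
#' @export
epoch <- function(rec, events, window_s = c(0, 0.02)) {
  stopifnot(inherits(rec, "ecap_recording"), inherits(events, "event_table"))
  if (length(window_s) != 2L || any(window_s < 0))
    stop("window_s must be two non-negative numbers (pre, post)")
  fs <- rec$sample_rate
  nw <- round(sum(window_s) * fs)
  if (nw < 1L) stop("zero-length epoch window")
  n <- ncol(rec$data)
  pre_samp <- floor(window_s[1] * fs)
  start <- round(events$time_s * fs) - pre_samp + 1L   # 1-based
  ok <- start >= 1L & (start + nw - 1L) <= n
  if (any(!ok))
    warning(sprintf("%d event(s) dropped: epoch window outside recording",
                    sum(!ok)))
  if (!any(ok)) stop("no event window fits inside the recording")
  keep <- which(ok)
  arr <- array(NA_real_, c(length(keep), nrow(rec$data), nw))
  for (i in seq_along(keep)) {
    idx <- start[keep[i]]:(start[keep[i]] + nw - 1L)
    arr[i, , ] <- rec$data[, idx]
  }
  ev <- events[keep, , drop = FALSE]
  class(ev) <- c("event_table", "data.frame")
  structure(
    list(data = arr, events = ev, window_s = window_s, sample_rate = fs,
         layout = rec$layout),
    class = "ecap_epochs")
}

#' @export
print.ecap_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ecap_epochs> %d events x %d channels x %d samples (%g to %g s)\n",
              d[1], d[2], d[3], -x$window_s[1], x$window_s[2]))
  invisible(x)
}
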