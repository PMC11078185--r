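#' Per-event, per-channel peak ECAP amplitudes
#'
#' For each event and channel, the largest detected spike amplitude whose
#' peak time falls inside the event's epoch window; 0 where no spike was
#' detected. This matrix is the substrate of the topographic maps and of
#' classification features.
#'
#' @param epochs an [epoch()] result (provides the event windows).
#' @param spikes data.frame with columns `channel`, `peak_time_s`,
#'   `peak_amplitude_uV` — e.g. [detect_session()]'s output.
#' @return Events x channels numeric matrix of class `peak_amplitude_map`,
#'   with the epochs' events and layout attached as attributes.
#' @export
peak_amplitudes <- function(epochs, spikes) {
  stopifnot(inherits(epochs, "ecap_epochs"))
  need <- c("channel", "peak_time_s", "peak_amplitude_uV")
  if (!all(need %in% names(spikes)))
    stop("spikes must have columns ", paste(need, collapse = ", "))
  nev <- nrow(epochs$events)
  nch <- dim(epochs$data)[2]
  if (nrow(spikes) && (any(spikes$channel < 1) || any(spikes$channel > nch)))
    stop("spike channel index outside the epoched channel range")
  m <- matrix(0, nev, nch)
  lo <- epochs$events$time_s - epochs$window_s[1]
  hi <- epochs$events$time_s + epochs$window_s[2]
  for (s in seq_len(nrow(spikes))) {
    e <- which(spikes$peak_time_s[s] >= lo & spikes$peak_time_s[s] < hi)
    if (length(e)) {
      ch <- spikes$channel[s]
      m[e, ch] <- pmax(m[e, ch], spikes$peak_amplitude_uV[s])
    }
  }
  structure(m, class = c("peak_amplitude_map", "matrix", "array"),
            events = epochs$events, layout = epochs$layout)
}

#' Interpolate one amplitude row onto a dense angular grid
#'
#' Piecewise-linear interpolation between adjacent electrodes on the
#' circle. With full circumferential coverage the interpolation wraps
#' around; with partial coverage no values are produced across the
#' uncovered gap. The grid always contains the electrode angles, where the
#' frame equals the input values exactly.
#'
#' @param values per-channel amplitudes (one map row).
#' @param layout the [electrode_layout()].
#' @param grid_step_deg angular grid step (default 1 degree).
#' @return An object of class `topo_frame`: data.frame with `angle_deg`
#'   and `amplitude_uV`, attribute `method = "linear"`.
#' @export
build_topoframe <- function(values, layout, grid_step_deg = 1) {
  stopifnot(inherits(layout, "electrode_layout"))
  if (grid_step_deg <= 0) stop("grid step must be positive")
  if (length(values) != layout$n_electrodes)
    stop("values length must equal the electrode count")
  ord <- order(layout$angles_deg)
  ang <- layout$angles_deg[ord]
  val <- values[ord]
  full <- layout$coverage_fraction >= 1
  if (full) {
    # wrap: duplicate first electrode one turn up
    ang_ext <- c(ang, ang[1] + 360)
    val_ext <- c(val, val[1])
    grid <- sort(unique(c(seq(-180, 180 - grid_step_deg, by = grid_step_deg),
                          ang)))
    grid_eval <- ifelse(grid < ang[1], grid + 360, grid)
    out <- approx(ang_ext, val_ext, xout = grid_eval, method = "linear")$y
  } else {
    grid <- sort(unique(c(seq(min(ang), max(ang), by = grid_step_deg), ang)))
    out <- approx(ang, val, xout = grid, method = "linear")$y
  }
  structure(data.frame(angle_deg = grid, amplitude_uV = out),
            class = c("topo_frame", "data.frame"),
            method = "linear", coverage_fraction = layout$coverage_fraction,
            electrode_spacing_deg = 360 * layout$coverage_fraction /
              layout$n_electrodes)
}

#' Localize the topographic hotspot(s) of a frame
#'
#' The primary hotspot is the frame's global maximum. An optional secondary
#' hotspot is the largest remaining local maximum at least
#' `min_separation_deg` away on the circle (motor sources project a
#' ventrolateral + lateral pair). A flat or all-zero frame yields a
#' flagged no-hotspot result rather than an error.
#'
#' @param frame a [build_topoframe()] result.
#' @param n_hotspots 1 or 2.
#' @param min_separation_deg minimum angular separation of the secondary
#'   hotspot (default 30 degrees).
#' @return A list: `found` flag, `angle_deg`, `magnitude_uV`, and (when
#'   `n_hotspots = 2`) `secondary_angle_deg`, `secondary_magnitude_uV`
#'   (NA when no separated second maximum exists).
#' @export
find_hotspot <- function(frame, n_hotspots = 1, min_separation_deg = 30) {
  stopifnot(inherits(frame, "topo_frame"), n_hotspots %in% c(1, 2))
  v <- frame$amplitude_uV
  if (!nrow(frame)) stop("empty frame")
  if (diff(range(v)) == 0)
    return(list(found = FALSE, angle_deg = NA_real_,
                magnitude_uV = NA_real_))
  imax <- which.max(v)
  out <- list(found = TRUE, angle_deg = frame$angle_deg[imax],
              magnitude_uV = v[imax])
  if (n_hotspots == 2) {
    n <- length(v)
    full <- attr(frame, "coverage_fraction") >= 1
    prv <- if (full) c(n, seq_len(n - 1L)) else c(1L, seq_len(n - 1L))
    nxt <- if (full) c(seq_len(n)[-1L], 1L) else c(seq_len(n)[-1L], n)
    locmax <- which(v >= v[prv] & v >= v[nxt])
    sep <- abs(wrap_angle(frame$angle_deg[locmax] - out$angle_deg))
    cand <- locmax[sep >= min_separation_deg]
    if (length(cand)) {
      j <- cand[which.max(v[cand])]
      out$secondary_angle_deg <- frame$angle_deg[j]
      out$secondary_magnitude_uV <- v[j]
    } else {
      out$secondary_angle_deg <- NA_real_
      out$secondary_magnitude_uV <- NA_real_
    }
  }
  out
}

#' Temporal evolution of the topographic map after stimulation
#'
#' Splits the epoch window into `floor(window / step)` consecutive time
#' bins and builds one topographic frame per bin from the event-averaged
#' mean amplitude of each channel within the bin, showing how the locus of
#' activation moves around the cord after the stimulus.
#'
#' @param epochs an [epoch()] result (typically of the denoised recording).
#' @param layout the [electrode_layout()]; defaults to the epochs' layout.
#' @param step_ms time-bin width in milliseconds.
#' @param events optional subset of event indices to average (default all).
#' @param grid_step_deg angular grid step for each frame.
#' @return A list of [build_topoframe()] frames; each carries attribute
#'   `time_s`, the bin start relative to the event.
#' @export
temporal_evolution <- function(epochs, layout = epochs$layout, step_ms,
                               events = NULL, grid_step_deg = 1) {
  stopifnot(inherits(epochs, "ecap_epochs"))
  nw <- dim(epochs$data)[3]
  step <- round(step_ms / 1000 * epochs$sample_rate)
  if (step < 1L || step > nw)
    stop("step must be positive and no larger than the epoch window")
  nframes <- nw %/% step
  if (is.null(events)) events <- seq_len(dim(epochs$data)[1])
  frames <- vector("list", nframes)
  for (f in seq_len(nframes)) {
    idx <- ((f - 1L) * step + 1L):(f * step)
    block <- epochs$data[events, , idx, drop = FALSE]
    chan_amp <- apply(block, 2, mean)
    fr <- build_topoframe(chan_amp, layout, grid_step_deg)
    attr(fr, "time_s") <- (f - 1L) * step / epochs$sample_rate -
      epochs$window_s[1]
    frames[[f]] <- fr
  }
  frames
}

#' @export
plot.topo_frame <- function(x, ...) {
  graphics::plot(x$angle_deg, x$amplitude_uV, type = "l",
                 xlab = "angle around cord (deg, 0 = dorsal midline)",
                 ylab = "amplitude (uV)", ...)
  invisible(x)
}
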