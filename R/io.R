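#' Write a recording to the package's container format
#'
#' The container is a single serialized file holding the data matrix in
#' microvolts, the sampling rate, the channel identifiers, the electrode
#' layout and any annotations. [read_recording()] restores it bit-identically.
#'
#' @param rec an [recording()] object.
#' @param path destination file path; an existing file is replaced.
#' @return Invisibly, `path`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "ecap_recording"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("parent directory does not exist: ", dir)
  payload <- list(format = "ecaptools-recording", version = 1L,
                  data = rec$data, sample_rate = rec$sample_rate,
                  channel_ids = rec$channel_ids,
                  layout = rec$layout, annotations = rec$annotations)
  saveRDS(payload, path)
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path file path of the container.
#' @return The restored [recording()] object.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  payload <- tryCatch(readRDS(path),
                      error = function(e) stop("malformed recording container: ",
                                               conditionMessage(e)))
  if (!is.list(payload) || !identical(payload$format, "ecaptools-recording"))
    stop("malformed recording container: not an ecaptools recording file")
  for (field in c("data", "sample_rate", "channel_ids")) {
    if (is.null(payload[[field]]))
      stop("recording container missing required field: ", field)
  }
  recording(payload$data, sample_rate = payload$sample_rate,
            channel_ids = payload$channel_ids, layout = payload$layout,
            annotations = if (is.null(payload$annotations)) list()
                          else payload$annotations)
}

#' Read / write stimulation event tables as CSV
#'
#' CSV with header `time_s,label,stim_amplitude_uA`. Labels must belong to
#' [SOURCE_LABELS] and times must be strictly increasing; both are validated
#' on read and on construction.
#'
#' @param path CSV file path.
#' @return `read_events()` returns an [event_table()].
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "label", "stim_amplitude_uA")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("event table missing column(s): ", paste(missing, collapse = ", "))
  event_table(df$time_s, df$label, df$stim_amplitude_uA)
}

#' @rdname read_events
#' @param events an [event_table()].
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "event_table"))
  write.csv(as.data.frame(events), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Session configuration
#'
#' A single nested list that parameterizes every pipeline stage: the
#' synthetic generator, preprocessing, denoising, detection, mapping,
#' classification and the bypass simulation, plus a global random seed.
#' See [default_session_config()] for the defaults and
#' the methods vignette for the rationale behind each value.
#'
#' @param path JSON file path.
#' @return `read_config()` returns the configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' @rdname read_config
#' @param config configuration list.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
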