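#' Construct a multichannel EEG recording
#'
#' The central container of the package: a channels-by-samples matrix in
#' microvolts with a sampling rate, per-channel type (EEG or EOG), and
#' cue events carrying four-class motor-imagery labels.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz.
#' @param channel_names character vector, one name per channel.
#' @param channel_types character vector of `"EEG"`/`"EOG"`, one per channel.
#' @param events data.frame with columns `sample` (1-based sample index of
#'   the cue) and `label` (integer class 1-4). May have zero rows.
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_names = NULL, channel_types = NULL,
                          events = NULL) {
  if (!is.matrix(data) || !is.numeric(data))
    stop_format("data must be a numeric channels x samples matrix")
  n_ch <- nrow(data)
  assert_scalar_num(fs, "fs", lo = 1e-9)
  if (is.null(channel_names)) channel_names <- sprintf("CH%02d", seq_len(n_ch))
  if (is.null(channel_types)) channel_types <- rep("EEG", n_ch)
  if (length(channel_names) != n_ch || length(channel_types) != n_ch)
    stop_format("channel_names/channel_types must match the channel count")
  if (!all(channel_types %in% c("EEG", "EOG")))
    stop_format("channel_types must be 'EEG' or 'EOG'")
  if (!any(channel_types == "EEG"))
    stop_format("recording must contain at least one EEG channel")
  if (is.null(events))
    events <- data.frame(sample = integer(0), label = integer(0))
  if (!all(c("sample", "label") %in% names(events)))
    stop_format("events must have columns 'sample' and 'label'")
  events <- data.frame(sample = as.integer(events$sample),
                       label = as.integer(events$label))
  if (nrow(events)) {
    if (any(events$label < 1L | events$label > 4L))
      stop_format("event label outside 1-4: found ",
                  paste(unique(events$label[events$label < 1 | events$label > 4]),
                        collapse = ", "))
    if (any(diff(events$sample) <= 0L))
      stop_format("event sample indices must be strictly increasing")
    if (events$sample[1] < 1L || events$sample[nrow(events)] > ncol(data))
      stop_format("event sample index outside the recording")
  }
  structure(list(data = data, fs = fs, channel_names = channel_names,
                 channel_types = channel_types, events = events),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels (%d EEG, %d EOG) x %d samples @ %g Hz, %d events\n",
              nrow(x$data), sum(x$channel_types == "EEG"),
              sum(x$channel_types == "EOG"), ncol(x$data), x$fs,
              nrow(x$events)))
  invisible(x)
}

#' Indices of EEG (non-EOG) channels
#' @param rec an `eeg_recording`.
#' @return integer vector.
#' @export
eeg_channels <- function(rec) which(rec$channel_types == "EEG")

#' Indices of EOG channels
#' @param rec an `eeg_recording`.
#' @return integer vector (possibly empty).
#' @export
eog_channels <- function(rec) which(rec$channel_types == "EOG")

#' Write a recording bundle
#'
#' The native on-disk format: `data.csv` holding the channels x samples
#' matrix (one row per channel, no header) and `meta.json` with the
#' sampling rate, channel names/types, and events. Sample indices are
#' stored 0-based in the sidecar for language neutrality.
#'
#' @param rec an `eeg_recording`.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(rec, dir) {
  stopifnot(inherits(rec, "eeg_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(rec$data, file.path(dir, "data.csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  meta <- list(
    fs = rec$fs,
    channel_names = rec$channel_names,
    channel_types = rec$channel_types,
    events = if (nrow(rec$events))
      data.frame(sample = rec$events$sample - 1L, label = rec$events$label)
    else list()
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a recording
#'
#' Reads the native bundle format written by [write_bundle()]. EDF/GDF
#' biosignal files are recognised as formats but no reader backend is
#' bundled; requesting them signals an informative error.
#'
#' @param path directory of a recording bundle (or file path for edf/gdf).
#' @param format one of `"bundle"`, `"edf"`, `"gdf"`.
#' @return an `eeg_recording`.
#' @export
read_recording <- function(path, format = c("bundle", "edf", "gdf")) {
  format <- match.arg(format)
  if (format %in% c("edf", "gdf"))
    stop_format("no ", format, " reader backend is available; convert to the ",
                "native bundle format (data.csv + meta.json)")
  meta_path <- file.path(path, "meta.json")
  data_path <- file.path(path, "data.csv")
  if (!file.exists(meta_path) || !file.exists(data_path))
    stop_format("bundle at ", path, " must contain data.csv and meta.json")
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (f in c("fs", "channel_names", "channel_types"))
    if (is.null(meta[[f]])) stop_format("bundle sidecar missing field '", f, "'")
  data <- as.matrix(utils::read.csv(data_path, header = FALSE))
  dimnames(data) <- NULL
  ev <- meta$events
  events <- if (is.null(ev) || length(ev) == 0L)
    data.frame(sample = integer(0), label = integer(0))
  else
    data.frame(sample = as.integer(ev$sample) + 1L, label = as.integer(ev$label))
  eeg_recording(data, fs = meta$fs, channel_names = meta$channel_names,
                channel_types = meta$channel_types, events = events)
}
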