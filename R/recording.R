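#' Construct a multichannel EEG recording
#'
#' The native in-memory container for continuous EEG: a channels x samples
#' matrix (microvolts) with a sampling rate, ordered channel labels and
#' per-trial event markers. Marker onsets are 0-based sample offsets into the
#' recording (the first sample has onset 0), so an epoch starting at a marker
#' covers samples `onset + 1 .. onset + N` in R's 1-based indexing.
#'
#' @param samples Numeric matrix, channels x samples.
#' @param fs Sampling rate in Hz.
#' @param channel_labels Character vector of unique channel names, one per row.
#' @param markers Data frame with columns `onset_sample` (0-based, strictly
#'   increasing) and `trial_index`.
#' @return An object of class `eeg_recording`.
#' @export
#' @examples
#' rec <- eeg_recording(matrix(0, 2, 512), fs = 256, c("O1", "O2"),
#'                      markers = data.frame(onset_sample = 0L, trial_index = 1L))
#' rec
eeg_recording <- function(samples, fs, channel_labels,
                          markers = data.frame(onset_sample = integer(0),
                                               trial_index = integer(0))) {
  samples <- as.matrix(samples)
  abort_if(!is.numeric(fs) || length(fs) != 1L || fs <= 0,
           "`fs` must be a single positive number")
  abort_if(length(channel_labels) != nrow(samples),
           "one channel label per sample row is required")
  abort_if(anyDuplicated(channel_labels) > 0L, "channel labels must be unique")
  abort_if(!all(c("onset_sample", "trial_index") %in% names(markers)),
           "markers need `onset_sample` and `trial_index` columns")
  if (nrow(markers) > 1L)
    abort_if(any(diff(markers$onset_sample) <= 0),
             "marker onsets must be strictly increasing")
  abort_if(nrow(markers) > 0L &&
             (any(markers$onset_sample < 0) ||
                any(markers$onset_sample >= max(ncol(samples), 1L))),
           "marker onsets must lie within the recording")
  rownames(samples) <- channel_labels
  structure(list(samples = samples, fs = fs,
                 channel_labels = as.character(channel_labels),
                 markers = as.data.frame(markers)),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %d markers\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              ncol(x$samples) / x$fs, nrow(x$markers)))
  invisible(x)
}

#' Construct a single labeled trial epoch
#'
#' One 5-s (at defaults) segment of multichannel EEG cut at a trial marker,
#' carrying its protocol metadata.
#'
#' @param samples Numeric matrix, channels x N.
#' @param fs Sampling rate in Hz.
#' @param condition `"attend-Gabor"`, `"attend-Face"` or `"feedback"`.
#' @param phase `"baseline1"`, `"baseline2"` or `"feedback"`.
#' @param trial_index Integer trial number within the session.
#' @param face_id Identifier of the face stimulus shown, or `NA`.
#' @param epoch_number Feedback-phase epoch (1-3), or `NA` for baseline.
#' @param exposure_count Position 1-5 within a face's consecutive run, or `NA`.
#' @return An object of class `trial_epoch`.
#' @export
trial_epoch <- function(samples, fs, condition, phase, trial_index,
                        face_id = NA_character_, epoch_number = NA_integer_,
                        exposure_count = NA_integer_) {
  samples <- as.matrix(samples)
  abort_if(fs <= 0, "`fs` must be positive")
  abort_if(!condition %in% c(CONDITIONS, "feedback"), "unknown condition")
  abort_if(!phase %in% c("baseline1", "baseline2", "feedback"), "unknown phase")
  ok <- switch(phase,
               baseline1 = condition == "attend-Gabor",
               baseline2 = condition == "attend-Face",
               feedback = condition == "feedback")
  abort_if(!ok, "condition `", condition, "` inconsistent with phase `", phase, "`")
  structure(list(samples = samples, fs = fs, condition = condition,
                 phase = phase, trial_index = as.integer(trial_index),
                 face_id = face_id, epoch_number = epoch_number,
                 exposure_count = exposure_count),
            class = "trial_epoch")
}

#' @export
print.trial_epoch <- function(x, ...) {
  cat(sprintf("<trial_epoch> trial %d [%s/%s] %d channels x %d samples @ %g Hz\n",
              x$trial_index, x$phase, x$condition,
              nrow(x$samples), ncol(x$samples), x$fs))
  invisible(x)
}

#' Write a recording to the native on-disk container
#'
#' Stores the sample matrix as a raw little-endian double array
#' (`<path>.dat`, channel-major) next to a JSON sidecar (`<path>.json`)
#' holding the sampling rate, channel labels, dimensions and markers.
#' The round trip is bit-exact.
#'
#' @param rec An [eeg_recording()].
#' @param path File path prefix (no extension).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  abort_if(!inherits(rec, "eeg_recording"), "`rec` must be an eeg_recording")
  meta <- list(format = "ssvepbci-rec-v1",
               dtype = "float64-le",
               order = "channel-major",
               n_channels = nrow(rec$samples),
               n_samples = ncol(rec$samples),
               fs = rec$fs,
               channel_labels = rec$channel_labels,
               markers = rec$markers)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con))
  # t() so the stream is channel-major: all samples of channel 1, then 2, ...
  writeBin(as.vector(t(rec$samples)), con, size = 8L, endian = "little")
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path File path prefix used when writing.
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  abort_if(!identical(meta$format, "ssvepbci-rec-v1"),
           "not a recognised recording container: ", path)
  n <- meta$n_channels * meta$n_samples
  con <- file(paste0(path, ".dat"), "rb")
  on.exit(close(con))
  x <- readBin(con, "double", n = n, size = 8L, endian = "little")
  abort_if(length(x) != n, "truncated sample array in ", path, ".dat")
  samples <- t(matrix(x, nrow = meta$n_samples, ncol = meta$n_channels))
  meta$fs <- as.numeric(meta$fs)
  markers <- as.data.frame(meta$markers)
  if (nrow(markers) == 0L)
    markers <- data.frame(onset_sample = integer(0), trial_index = integer(0))
  eeg_recording(samples, meta$fs, meta$channel_labels, markers)
}

#' Write a trial label table as CSV
#'
#' @param labels Data frame of per-trial metadata (trial_index, phase,
#'   condition, face_id, onset_sample, ...).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  write.csv(labels, path, row.names = FALSE)
  invisible(path)
}

#' Read a trial label table written by [write_labels()]
#' @param path CSV path.
#' @return Data frame.
#' @export
read_labels <- function(path) read.csv(path, stringsAsFactors = FALSE)
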