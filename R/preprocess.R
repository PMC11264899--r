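#' Design the Kaiser-window FIR bandpass filter
#'
#' Linear-phase FIR bandpass designed with a Kaiser window for the standard
#' [1, 40] Hz EEG analysis band. Transition edges are placed at
#' `0.75*low` / `2*low` below and `high - 2` / `high + 5` above the band, with
#' deviation targets of 0.001 in the stopbands (>= 60 dB design goal, and in
#' any case >= 40 dB at 0.5 Hz and 45 Hz at the defaults) and 0.0575 in the
#' passband (<= 1 dB ripple). The realised mask is checked at design time.
#'
#' @param fs Sampling rate in Hz.
#' @param low,high Passband edges in Hz; `0 < low < high < fs/2` and the upper
#'   stopband edge `high + 5` must stay below Nyquist.
#' @return An object of class `fir_spec`: coefficients `b`, `order`, `fs`,
#'   the band and the design targets (logged so output metadata can carry
#'   them).
#' @export
#' @examples
#' spec <- design_bandpass(256)
#' spec$order
design_bandpass <- function(fs, low = 1, high = 40) {
  abort_if(!(low > 0 && low < high && high < fs / 2),
           "band [", low, ", ", high, "] Hz must satisfy 0 < low < high < fs/2")
  edges <- c(0.75 * low, 2 * low, high - 2, high + 5)
  abort_if(edges[4] >= fs / 2,
           "upper transition band exceeds Nyquist; lower `high` or raise `fs`")
  dev <- c(0.001, 0.0575, 0.001)
  ko <- signal::kaiserord(edges, c(0, 1, 0), dev, fs)
  ord <- ko$n + (ko$n %% 2L)  # even order -> odd-length symmetric (type I) FIR
  b <- as.numeric(signal::fir1(ord, ko$Wc, type = "pass",
                               window = signal::kaiser(ord + 1, ko$beta)))
  structure(list(b = b, order = ord, fs = fs, low = low, high = high,
                 transition_edges = edges, dev = dev, beta = ko$beta,
                 design = "kaiser-fir-bandpass"),
            class = "fir_spec")
}

#' @export
print.fir_spec <- function(x, ...) {
  cat(sprintf("<fir_spec> Kaiser FIR bandpass [%g, %g] Hz, order %d @ %g Hz\n",
              x$low, x$high, x$order, x$fs))
  invisible(x)
}

# Complex frequency response of an FIR at frequency f (Hz).
fir_response <- function(spec, f) {
  k <- 0:spec$order
  vapply(f, function(fi) abs(sum(spec$b * exp(-2i * pi * fi / spec$fs * k))),
         numeric(1))
}

#' Apply a bandpass filter to a recording, zero phase
#'
#' Forward-backward application ([signal::filtfilt()]) of the designed FIR, so
#' the passband phase of the frequency tags is not distorted. Shape, channel
#' order and markers are preserved.
#'
#' @param rec An [eeg_recording()].
#' @param spec A `fir_spec` from [design_bandpass()] designed at `rec$fs`.
#' @return A filtered [eeg_recording()].
#' @export
apply_filter <- function(rec, spec) {
  abort_if(!inherits(rec, "eeg_recording"), "`rec` must be an eeg_recording")
  abort_if(!inherits(spec, "fir_spec"), "`spec` must come from design_bandpass()")
  abort_if(!isTRUE(all.equal(spec$fs, rec$fs)),
           "filter was designed for fs = ", spec$fs, " Hz, recording is ",
           rec$fs, " Hz")
  abort_if(ncol(rec$samples) < 3L * spec$order,
           "recording too short to filter: need at least ", 3L * spec$order,
           " samples (3x filter order), have ", ncol(rec$samples))
  out <- rec$samples
  for (ch in seq_len(nrow(out)))
    out[ch, ] <- signal::filtfilt(spec$b, 1, rec$samples[ch, ])
  eeg_recording(out, rec$fs, rec$channel_labels, rec$markers)
}

#' Cut a continuous recording into per-trial epochs
#'
#' One epoch per marker, starting exactly at the marker sample (0-based
#' onsets), `N = round(fs * duration)` samples long, channel order preserved,
#' no baseline correction. Trial metadata is joined from `labels` by
#' `trial_index` when supplied.
#'
#' @param rec An [eeg_recording()].
#' @param duration Epoch length in seconds.
#' @param labels Optional label table (as produced by [simulate_session()] or
#'   [build_schedule()]) supplying phase/condition/face metadata per trial.
#' @return List of [trial_epoch()] objects, in marker order.
#' @export
epoch_recording <- function(rec, duration = 5, labels = NULL) {
  abort_if(!inherits(rec, "eeg_recording"), "`rec` must be an eeg_recording")
  abort_if(duration <= 0, "`duration` must be positive")
  n <- round(rec$fs * duration)
  mk <- rec$markers
  if (nrow(mk) == 0L) return(list())
  over <- which(mk$onset_sample + n > ncol(rec$samples))
  abort_if(length(over) > 0L,
           "trial ", mk$trial_index[over[1]], " overruns the recording end (",
           "needs samples up to ", mk$onset_sample[over[1]] + n, " of ",
           ncol(rec$samples), ")")
  lapply(seq_len(nrow(mk)), function(i) {
    idx <- (mk$onset_sample[i] + 1):(mk$onset_sample[i] + n)
    meta <- list(condition = "attend-Gabor", phase = "baseline1",
                 face_id = NA_character_, epoch_number = NA_integer_,
                 exposure_count = NA_integer_)
    if (!is.null(labels)) {
      row <- labels[labels$trial_index == mk$trial_index[i], , drop = FALSE]
      abort_if(nrow(row) != 1L, "trial ", mk$trial_index[i],
               " missing from (or duplicated in) the label table")
      meta$condition <- row$condition
      meta$phase <- row$phase
      meta$face_id <- row$face_id
      if ("epoch_number" %in% names(row)) meta$epoch_number <- row$epoch_number
      if ("exposure_count" %in% names(row)) meta$exposure_count <- row$exposure_count
    }
    trial_epoch(rec$samples[, idx, drop = FALSE], rec$fs,
                condition = meta$condition, phase = meta$phase,
                trial_index = mk$trial_index[i], face_id = meta$face_id,
                epoch_number = meta$epoch_number,
                exposure_count = meta$exposure_count)
  })
}
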