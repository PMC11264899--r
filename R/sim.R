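#' Configuration for the synthetic frequency-tagged EEG generator
#'
#' Defines the stimulus regime the simulator emulates: two superimposed
#' flickering stimuli — an affective face tagged at 8.57 Hz and a Gabor patch
#' tagged at 12 Hz — evoking steady-state responses at the tag frequencies and
#' their harmonics, strongest over occipital cortex, embedded in 1/f^beta
#' background noise. The attended stimulus receives the larger amplitude
#' weight, which is what a decoder must pick up.
#'
#' @param f_face Face tag frequency in Hz.
#' @param f_gabor Gabor tag frequency in Hz.
#' @param fs Sampling rate in Hz.
#' @param trial_duration Trial length in seconds; `fs * trial_duration` must be
#'   a whole number of samples.
#' @param n_harmonics_sim Number of harmonics generated per tag.
#' @param harmonic_rolloff Amplitude ratio between successive harmonic orders
#'   (harmonic h has relative amplitude `harmonic_rolloff^(h-1)`).
#' @param attention_weights Named pair `c(attended=, unattended=)` of
#'   non-negative multipliers applied to a tag's full harmonic stack according
#'   to which stimulus the trial's condition attends.
#' @param snr Ratio of the attended tag's fundamental amplitude (1 uV by
#'   construction) to the per-channel background-noise standard deviation.
#'   `Inf` disables noise.
#' @param noise_exponent Spectral slope beta of the 1/f^beta pink component.
#' @param channel_gains Named numeric vector of per-channel gains applied to
#'   the tag content (topography). Defaults to gain 1 on O1/O2/Oz and 0.3 on
#'   the 16 non-occipital recorded channels.
#' @param seed Default seed used when an operation is not given one.
#' @return An object of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(snr = 2)
#' ep <- simulate_epoch(cfg, "attend-Gabor", seed = 1)
#' dim(ep$samples)
sim_config <- function(f_face = 8.57, f_gabor = 12, fs = 256,
                       trial_duration = 5, n_harmonics_sim = 3,
                       harmonic_rolloff = 0.5,
                       attention_weights = c(attended = 1, unattended = 0.3),
                       snr = 1, noise_exponent = 1,
                       channel_gains = default_channel_gains(),
                       seed = 1L) {
  abort_if(fs <= 0 || trial_duration <= 0,
           "invalid config: `fs` and `trial_duration` must be positive")
  abort_if(abs(fs * trial_duration - round(fs * trial_duration)) > 1e-9,
           "invalid config: `trial_duration * fs` must be an integer sample count")
  abort_if(fs <= 2 * n_harmonics_sim * max(f_face, f_gabor),
           "invalid config: highest simulated harmonic violates Nyquist")
  abort_if(length(attention_weights) != 2L || any(attention_weights < 0),
           "invalid config: `attention_weights` must be two non-negative values")
  if (is.null(names(attention_weights)))
    names(attention_weights) <- c("attended", "unattended")
  abort_if(!all(c("attended", "unattended") %in% names(attention_weights)),
           "invalid config: weights must be named attended/unattended")
  abort_if(is.null(names(channel_gains)) || any(channel_gains < 0),
           "invalid config: `channel_gains` must be named and non-negative")
  abort_if(snr <= 0, "invalid config: `snr` must be positive (Inf for no noise)")
  structure(list(f_face = f_face, f_gabor = f_gabor, fs = fs,
                 trial_duration = trial_duration,
                 n_harmonics_sim = as.integer(n_harmonics_sim),
                 harmonic_rolloff = harmonic_rolloff,
                 attention_weights = attention_weights[c("attended", "unattended")],
                 snr = snr, noise_exponent = noise_exponent,
                 channel_gains = channel_gains, seed = as.integer(seed)),
            class = "sim_config")
}

#' Default simulated topography over the 19-channel montage
#'
#' Occipital channels (O1, O2, Oz), which overlie primary visual cortex where
#' the steady-state response is generated, carry the tags at full gain; the 16
#' other recorded sites receive attenuated tag content.
#'
#' @param occipital_gain Gain on O1/O2/Oz.
#' @param other_gain Gain on the remaining channels.
#' @return Named numeric vector over the 19-channel montage.
#' @export
default_channel_gains <- function(occipital_gain = 1, other_gain = 0.3) {
  g <- setNames(rep(other_gain, length(MONTAGE_19)), MONTAGE_19)
  g[OCCIPITAL_CHANNELS] <- occipital_gain
  g
}

# 1/f^(beta) noise via spectral shaping of white Gaussian noise; unit variance.
pink_noise <- function(n, beta) {
  if (n < 2L) return(rnorm(n))
  w <- rnorm(n)
  X <- fft(w)
  k <- seq_len(n) - 1L
  f <- pmin(k, n - k)              # two-sided frequency index, bin units
  shape <- c(0, 1 / f[-1]^(beta / 2))  # kill DC, shape amplitude as f^(-beta/2)
  x <- Re(fft(X * shape, inverse = TRUE)) / n
  s <- sd(x)
  if (s == 0) x else x / s
}

# Sum of harmonic sinusoids for one tag: fundamental f, random reference phase
# phi applied as h*phi (a phase-shifted periodic waveform), rolloff per order.
tag_waveform <- function(t, f, phi, n_harmonics, rolloff) {
  x <- numeric(length(t))
  for (h in seq_len(n_harmonics))
    x <- x + rolloff^(h - 1) * sin(2 * pi * h * f * t + h * phi)
  x
}

#' Simulate one labeled frequency-tagged trial epoch
#'
#' Generates a channels x samples epoch containing both tags at all configured
#' harmonics. The tag matching the trial's attended stimulus is scaled by
#' `attention_weights["attended"]`, the other by `["unattended"]`; each tag
#' gets an independent uniform random phase per trial. Background noise is an
#' equal-variance mix of 1/f^beta pink noise and white Gaussian noise drawn
#' independently per channel, with standard deviation `1/snr`. Identical
#' `(config, condition, seed)` give bit-identical epochs.
#'
#' @param config A [sim_config()].
#' @param condition `"attend-Gabor"` or `"attend-Face"`.
#' @param seed Integer seed (defaults to `config$seed`).
#' @param trial_index,phase,face_id,epoch_number,exposure_count Metadata
#'   attached to the returned epoch.
#' @return A [trial_epoch()].
#' @export
simulate_epoch <- function(config, condition = c("attend-Gabor", "attend-Face"),
                           seed = config$seed, trial_index = 1L,
                           phase = NULL, face_id = NA_character_,
                           epoch_number = NA_integer_,
                           exposure_count = NA_integer_) {
  abort_if(!inherits(config, "sim_config"), "`config` must be a sim_config")
  condition <- match.arg(condition)
  if (is.null(phase))
    phase <- if (condition == "attend-Gabor") "baseline1" else "baseline2"
  n <- round(config$fs * config$trial_duration)
  t <- (seq_len(n) - 1) / config$fs
  aw <- config$attention_weights
  w_gabor <- unname(if (condition == "attend-Gabor") aw["attended"] else aw["unattended"])
  w_face <- unname(if (condition == "attend-Face") aw["attended"] else aw["unattended"])

  labels <- names(config$channel_gains)
  samples <- with_seed(seed, {
    phi <- runif(2, 0, 2 * pi)       # one reference phase per tag
    src <- w_face * tag_waveform(t, config$f_face, phi[1],
                                 config$n_harmonics_sim, config$harmonic_rolloff) +
      w_gabor * tag_waveform(t, config$f_gabor, phi[2],
                             config$n_harmonics_sim, config$harmonic_rolloff)
    out <- outer(unname(config$channel_gains), src)
    if (is.finite(config$snr)) {
      sigma <- 1 / config$snr
      for (ch in seq_along(labels)) {
        noise <- (pink_noise(n, config$noise_exponent) + rnorm(n)) / sqrt(2)
        out[ch, ] <- out[ch, ] + sigma * noise
      }
    }
    out
  })
  rownames(samples) <- labels
  trial_epoch(samples, config$fs,
              condition = if (phase == "feedback") "feedback" else condition,
              phase = phase, trial_index = trial_index, face_id = face_id,
              epoch_number = epoch_number, exposure_count = exposure_count)
}

#' Simulate a full session as one continuous recording
#'
#' Walks a protocol schedule (see [build_schedule()]), simulates each trial
#' back-to-back and concatenates the epochs into a continuous
#' [eeg_recording()] with one marker per trial, plus the label table.
#' Feedback-phase trials are simulated under `feedback_attention` (the
#' protocol instructs participants to attend the Gabor).
#'
#' @param config A [sim_config()].
#' @param schedule A session schedule data frame from [build_schedule()].
#' @param seed Integer master seed; per-trial seeds are derived from it.
#' @param feedback_attention Condition simulated during feedback trials.
#' @return List with elements `recording` ([eeg_recording()]) and `labels`
#'   (data frame: trial_index, phase, condition, face_id, epoch_number,
#'   exposure_count, onset_sample).
#' @export
simulate_session <- function(config, schedule, seed = config$seed,
                             feedback_attention = "attend-Gabor") {
  abort_if(!inherits(config, "sim_config"), "`config` must be a sim_config")
  abort_if(!is.data.frame(schedule) ||
             !all(c("trial_index", "phase", "condition", "face_id") %in%
                    names(schedule)),
           "`schedule` must be a session schedule data frame")
  n_trials <- nrow(schedule)
  n <- round(config$fs * config$trial_duration)
  labels <- names(config$channel_gains)
  if (n_trials == 0L) {
    return(list(recording = eeg_recording(matrix(0, length(labels), 0),
                                          config$fs, labels),
                labels = cbind(schedule, onset_sample = integer(0))))
  }
  seeds <- derive_seeds(seed, n_trials)
  samples <- matrix(0, length(labels), n * n_trials)
  for (i in seq_len(n_trials)) {
    row <- schedule[i, ]
    sim_cond <- if (row$condition == "feedback") feedback_attention else row$condition
    ep <- simulate_epoch(config, sim_cond, seed = seeds[i],
                         trial_index = row$trial_index, phase = row$phase,
                         face_id = row$face_id,
                         epoch_number = row$epoch_number,
                         exposure_count = row$exposure_count)
    samples[, ((i - 1) * n + 1):(i * n)] <- ep$samples
  }
  onsets <- (seq_len(n_trials) - 1L) * n
  rec <- eeg_recording(samples, config$fs, labels,
                       markers = data.frame(onset_sample = onsets,
                                            trial_index = schedule$trial_index))
  lab <- schedule
  lab$onset_sample <- onsets
  list(recording = rec, labels = lab)
}
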