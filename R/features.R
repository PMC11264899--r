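#' Configure a feature family
#'
#' Three families of frequency-tagging features are supported, all computed
#' from the raw FFT of the (already bandpass-filtered) epoch with FFT length
#' equal to the epoch length (no zero padding; 0.2 Hz bins at the defaults):
#'
#' * `"psd"` — power spectral density `(1/N) |X(f)|^2` of the time-domain
#'   average of the configured channels, one feature per one-sided bin in
#'   the 1-40 Hz analysis band.
#' * `"power_bank"` — for each channel, tag frequency and harmonic
#'   `h = 1..n_harmonics`, band power in `[h*f - f0, h*f + f0]` normalized by
#'   the channel's total one-sided power (DC excluded); values in [0, 1].
#' * `"cosine_corr"` — Pearson correlation of each channel with a cosine
#'   template `cos(2*pi*h*f*t)`, `t = (0..N-1)/fs`, phase 0; values in
#'   [-1, 1].
#'
#' Band membership is decided purely on FFT bin centers (closed interval), so
#' the off-grid 8.57 Hz tag maps to a deterministic bin set.
#'
#' @param family One of `"power_bank"`, `"psd"`, `"cosine_corr"`.
#' @param n_harmonics Number of harmonics per tag (power bank / cosine
#'   correlation), 1-3 in the standard menu.
#' @param f0 Half-bandwidth of each harmonic band in Hz (power bank).
#' @param tag_frequencies Named vector of the two tag fundamentals.
#' @param channels Channels features are extracted from (occipital by
#'   default).
#' @param use_feature_selection Whether decoding with this configuration runs
#'   forward feature selection before training.
#' @return An object of class `feature_config`.
#' @export
#' @examples
#' feature_config("power_bank", n_harmonics = 3, f0 = 2)
feature_config <- function(family = c("power_bank", "psd", "cosine_corr"),
                           n_harmonics = 3, f0 = 2,
                           tag_frequencies = TAG_FREQUENCIES,
                           channels = OCCIPITAL_CHANNELS,
                           use_feature_selection = FALSE) {
  family <- match.arg(family)
  abort_if(n_harmonics < 1, "`n_harmonics` must be >= 1")
  abort_if(f0 <= 0, "`f0` must be positive")
  abort_if(length(channels) == 0L, "`channels` must be non-empty")
  abort_if(length(tag_frequencies) != 2L || any(tag_frequencies <= 0),
           "`tag_frequencies` must be two positive frequencies")
  if (is.null(names(tag_frequencies)))
    names(tag_frequencies) <- c("face", "gabor")
  structure(list(family = family, n_harmonics = as.integer(n_harmonics),
                 f0 = f0, tag_frequencies = tag_frequencies,
                 channels = channels,
                 use_feature_selection = isTRUE(use_feature_selection)),
            class = "feature_config")
}

#' @export
print.feature_config <- function(x, ...) {
  cat(sprintf("<feature_config> %s (n = %d, f0 = %g%s) on %s\n",
              x$family, x$n_harmonics, x$f0,
              if (x$use_feature_selection) ", FS" else "",
              paste(x$channels, collapse = "/")))
  invisible(x)
}

# One-sided FFT power of a vector: |X_k|^2 for k = 0..floor(N/2), with the
# bin-center frequencies. Raw |X|^2, not density-scaled; callers normalize.
onesided_power <- function(x, fs) {
  n <- length(x)
  X <- fft(x)
  k <- 0:(n %/% 2)
  list(freq = k * fs / n, power = Mod(X[k + 1])^2)
}

check_channels <- function(epoch, channels) {
  missing <- setdiff(channels, rownames(epoch$samples))
  abort_if(length(missing) > 0L,
           "channel(s) ", paste(missing, collapse = ", "),
           " missing from epoch")
}

#' Power spectral density features
#'
#' Averages the configured channels in the time domain, takes the FFT of the
#' average, and returns `(1/N)|X(f)|^2` for every one-sided bin whose center
#' lies in the 1-40 Hz analysis band.
#'
#' @param epoch A [trial_epoch()].
#' @param cfg A [feature_config()] with `family = "psd"`.
#' @return Named numeric vector of non-negative band powers.
#' @export
psd_features <- function(epoch, cfg) {
  abort_if(cfg$family != "psd", "`cfg` is not a PSD configuration")
  check_channels(epoch, cfg$channels)
  avg <- colMeans(epoch$samples[cfg$channels, , drop = FALSE])
  sp <- onesided_power(avg, epoch$fs)
  keep <- sp$freq >= 1 & sp$freq <= 40
  v <- sp$power[keep] / length(avg)
  names(v) <- sprintf("psd_%.1fHz", sp$freq[keep])
  v
}

#' Harmonic band-power (power bank) features
#'
#' For each configured channel, tag frequency and harmonic order
#' `h = 1..n_harmonics`, sums the one-sided FFT power over bins whose centers
#' fall in the closed band `[h*f - f0, h*f + f0]` and divides by the
#' channel's total one-sided power excluding DC. Every value lies in [0, 1].
#'
#' @inheritParams psd_features
#' @param cfg A [feature_config()] with `family = "power_bank"`.
#' @return Named numeric vector of `length(channels) * 2 * n_harmonics`
#'   ratios.
#' @export
power_bank_features <- function(epoch, cfg) {
  abort_if(cfg$family != "power_bank", "`cfg` is not a power-bank configuration")
  check_channels(epoch, cfg$channels)
  nyq <- epoch$fs / 2
  hi <- cfg$n_harmonics * max(cfg$tag_frequencies) + cfg$f0
  abort_if(hi >= nyq, "band edge ", hi, " Hz exceeds Nyquist (", nyq, " Hz)")
  out <- numeric(0)
  for (ch in cfg$channels) {
    sp <- onesided_power(epoch$samples[ch, ], epoch$fs)
    total <- sum(sp$power[-1])  # one-sided total, DC excluded
    for (tag in names(cfg$tag_frequencies)) {
      f <- cfg$tag_frequencies[[tag]]
      for (h in seq_len(cfg$n_harmonics)) {
        inband <- sp$freq >= h * f - cfg$f0 & sp$freq <= h * f + cfg$f0
        val <- if (total > 0) sum(sp$power[inband & sp$freq > 0]) / total else 0
        out[sprintf("pb_%s_%s_h%d", ch, tag, h)] <- val
      }
    }
  }
  out
}

#' Cosine-template correlation features
#'
#' Pearson correlation between each configured channel's time series and a
#' phase-zero cosine at each tag harmonic, `cos(2*pi*h*f*t)` with
#' `t = (0..N-1)/fs`. A constant (zero-variance) channel yields 0 with a
#' warning.
#'
#' @inheritParams psd_features
#' @param cfg A [feature_config()] with `family = "cosine_corr"`.
#' @return Named numeric vector of correlations in [-1, 1].
#' @export
cosine_corr_features <- function(epoch, cfg) {
  abort_if(cfg$family != "cosine_corr",
           "`cfg` is not a cosine-correlation configuration")
  check_channels(epoch, cfg$channels)
  n <- ncol(epoch$samples)
  t <- (seq_len(n) - 1) / epoch$fs
  out <- numeric(0)
  for (ch in cfg$channels) {
    x <- epoch$samples[ch, ]
    zero_var <- var(x) == 0
    if (zero_var)
      warning("channel ", ch, " has zero variance; correlations set to 0",
              call. = FALSE)
    for (tag in names(cfg$tag_frequencies)) {
      f <- cfg$tag_frequencies[[tag]]
      for (h in seq_len(cfg$n_harmonics)) {
        template <- cos(2 * pi * h * f * t)
        out[sprintf("cc_%s_%s_h%d", ch, tag, h)] <-
          if (zero_var) 0 else cor(x, template)
      }
    }
  }
  out
}

#' Extract the configured feature vector from one epoch
#'
#' Dispatches to [psd_features()], [power_bank_features()] or
#' [cosine_corr_features()] according to `cfg$family`.
#'
#' @inheritParams psd_features
#' @param cfg A [feature_config()].
#' @return Named numeric feature vector.
#' @export
extract_features <- function(epoch, cfg) {
  switch(cfg$family,
         psd = psd_features(epoch, cfg),
         power_bank = power_bank_features(epoch, cfg),
         cosine_corr = cosine_corr_features(epoch, cfg))
}

#' Assemble a trials x features matrix from a list of epochs
#'
#' Rows are ordered by `trial_index`; feature names are deterministic given
#' the configuration. All epochs must share montage and length.
#'
#' @param epochs List of [trial_epoch()] objects.
#' @param cfg A [feature_config()].
#' @return An object of class `feature_matrix`: `values` (trials x features
#'   matrix), `feature_names`, `labels` (per-trial condition), `trial_index`
#'   and the `config`.
#' @export
assemble_feature_matrix <- function(epochs, cfg) {
  abort_if(length(epochs) == 0L, "`epochs` must be a non-empty list")
  ns <- vapply(epochs, function(e) ncol(e$samples), integer(1))
  abort_if(length(unique(ns)) != 1L, "epochs have mixed lengths: ",
           paste(unique(ns), collapse = ", "))
  ord <- order(vapply(epochs, function(e) e$trial_index, integer(1)))
  epochs <- epochs[ord]
  rows <- lapply(epochs, extract_features, cfg = cfg)
  values <- do.call(rbind, rows)
  rownames(values) <- NULL
  structure(list(values = values,
                 feature_names = colnames(values),
                 labels = vapply(epochs, function(e) e$condition, character(1)),
                 trial_index = vapply(epochs, function(e) e$trial_index,
                                      integer(1)),
                 config = cfg),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d trials x %d features (%s)\n",
              nrow(x$values), ncol(x$values), x$config$family))
  invisible(x)
}

#' Write a feature matrix as CSV plus a JSON config block
#'
#' @param fm A `feature_matrix`.
#' @param path Output path prefix; writes `<path>.csv` (header row of feature
#'   names, plus trial_index and label columns) and `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(trial_index = fm$trial_index, label = fm$labels,
                   fm$values, check.names = FALSE)
  write.csv(df, paste0(path, ".csv"), row.names = FALSE)
  cfg <- fm$config
  cfg$tag_frequencies <- as.list(cfg$tag_frequencies)
  jsonlite::write_json(unclass(cfg), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
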