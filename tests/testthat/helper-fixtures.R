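# Shared fixtures: small deterministic signals and scaled-down simulations.

FS <- 256

# A trial epoch whose channels are arbitrary supplied signals (defaults to a
# pure 12 Hz cosine on the three occipital channels).
tone_epoch <- function(signal = NULL, fs = FS, duration = 5,
                       channels = c("O1", "O2", "Oz"), trial_index = 1L,
                       condition = "attend-Gabor", phase = "baseline1") {
  n <- fs * duration
  t <- (seq_len(n) - 1) / fs
  if (is.null(signal)) signal <- cos(2 * pi * 12 * t)
  m <- matrix(rep(signal, length.out = length(channels) * n),
              nrow = length(channels), byrow = TRUE)
  rownames(m) <- channels
  trial_epoch(m, fs, condition, phase, trial_index)
}

# Independent one-sided DFT oracle: band power of x in [lo, hi] Hz by direct
# summation of the DFT definition (no fft()).
dft_band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  ks <- 0:(n %/% 2)
  freqs <- ks * fs / n
  keep <- freqs >= lo & freqs <= hi
  sum(vapply(ks[keep], function(k) {
    Mod(sum(x * exp(-2i * pi * k * (0:(n - 1)) / n)))^2
  }, numeric(1)))
}

# Brute-force Pearson correlation via the covariance formula.
pearson_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Small, fast simulated baseline: n_per_condition trials per condition at the
# given contrast, features straight off the raw simulated epochs (no filter;
# the simulator is already band-limited to the tags plus noise).
sim_baseline_epochs <- function(seed, n_per_condition = 15,
                                attended = 1, unattended = 0.3, snr = 1,
                                duration = 5) {
  cfg <- sim_config(trial_duration = duration, snr = snr,
                    attention_weights = c(attended = attended,
                                          unattended = unattended))
  seeds <- ssvepbci:::derive_seeds(seed, 2 * n_per_condition)
  eps <- vector("list", 2 * n_per_condition)
  for (i in seq_len(n_per_condition)) {
    eps[[2 * i - 1]] <- simulate_epoch(cfg, "attend-Gabor",
                                       seed = seeds[2 * i - 1],
                                       trial_index = 2L * i - 1L)
    eps[[2 * i]] <- simulate_epoch(cfg, "attend-Face", seed = seeds[2 * i],
                                   trial_index = 2L * i)
  }
  eps
}

# Well-separated two-class Gaussian feature matrix for decoder unit tests.
gaussian_features <- function(seed, n_per_class = 30, p = 4, shift = 4) {
  ssvepbci:::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per_class * p), n_per_class),
               matrix(rnorm(n_per_class * p, mean = shift), n_per_class))
    colnames(x) <- paste0("f", seq_len(p))
    list(x = x,
         labels = rep(c("attend-Gabor", "attend-Face"), each = n_per_class))
  })
}
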