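psd_cfg <- feature_config("psd")
pb_cfg <- feature_config("power_bank", n_harmonics = 3, f0 = 2)
cc_cfg <- feature_config("cosine_corr", n_harmonics = 3)

test_that("PSD of an all-zero epoch is all zero and non-negative elsewhere", {
  z <- tone_epoch(signal = numeric(FS * 5))
  expect_true(all(psd_features(z, psd_cfg) == 0))
  noisy <- tone_epoch(signal = ssvepbci:::with_seed(1, rnorm(FS * 5)))
  expect_true(all(psd_features(noisy, psd_cfg) >= 0))
})

test_that("the PSD 12 Hz bin equals the brute-force DFT oracle to 1e-9", {
  ep <- tone_epoch()  # unit 12 Hz cosine on every channel
  v <- psd_features(ep, psd_cfg)
  n <- FS * 5
  # 12 Hz bin index: k = 12 / (fs/n)
  x <- colMeans(ep$samples[psd_cfg$channels, ])
  k <- 12 * n / FS
  oracle <- Mod(sum(x * exp(-2i * pi * k * (0:(n - 1)) / n)))^2 / n
  expect_equal(unname(v["psd_12.0Hz"]), oracle, tolerance = 1e-9)
  expect_equal(unname(which.max(v)), which(names(v) == "psd_12.0Hz"))
})

test_that("PSD is invariant to channel permutation of the same signals", {
  n <- FS * 5
  sigs <- ssvepbci:::with_seed(3, matrix(rnorm(3 * n), 3))
  m1 <- sigs; rownames(m1) <- c("O1", "O2", "Oz")
  m2 <- sigs[c(3, 1, 2), ]; rownames(m2) <- c("O1", "O2", "Oz")
  e1 <- trial_epoch(m1, FS, "attend-Gabor", "baseline1", 1L)
  e2 <- trial_epoch(m2, FS, "attend-Gabor", "baseline1", 1L)
  expect_equal(psd_features(e1, psd_cfg), psd_features(e2, psd_cfg))
})

test_that("power-bank ratios isolate a pure tone in its own band", {
  ep <- tone_epoch()  # pure 12 Hz
  cfg1 <- feature_config("power_bank", n_harmonics = 1, f0 = 2)
  v <- power_bank_features(ep, cfg1)
  expect_gte(unname(v["pb_O1_gabor_h1"]), 0.99)
  expect_lte(unname(v["pb_O1_face_h1"]), 0.01)
})

test_that("power-bank ratios are in [0,1] and disjoint bands sum to at most 1", {
  ep <- tone_epoch(signal = ssvepbci:::with_seed(8, rnorm(FS * 5)))
  v <- power_bank_features(ep, pb_cfg)
  expect_true(all(v >= 0 & v <= 1))
  # gabor bands 12/24/36 +/- 2 Hz are disjoint on one channel
  gabor_o1 <- v[grep("pb_O1_gabor", names(v))]
  expect_lte(sum(gabor_o1), 1)
})

test_that("power-bank band membership follows the DFT oracle for the off-grid tag", {
  x <- ssvepbci:::with_seed(5, sin(2 * pi * 8.57 * (0:(FS * 5 - 1)) / FS) +
                              0.3 * rnorm(FS * 5))
  ep <- tone_epoch(signal = x)
  cfg1 <- feature_config("power_bank", n_harmonics = 1, f0 = 2)
  v <- power_bank_features(ep, cfg1)
  oracle <- dft_band_power(x, FS, 8.57 - 2, 8.57 + 2) /
    (dft_band_power(x, FS, 0, FS / 2) -
       Mod(sum(x))^2)  # DC excluded from the total
  expect_equal(unname(v["pb_O1_face_h1"]), oracle, tolerance = 1e-9)
})

test_that("bands beyond Nyquist are rejected", {
  ep <- tone_epoch()
  bad <- feature_config("power_bank", n_harmonics = 11, f0 = 2)
  expect_error(power_bank_features(ep, bad), "Nyquist")
})

test_that("cosine correlation is exact for matched, quadrature and noisy signals", {
  n <- FS * 5
  t <- (0:(n - 1)) / FS
  cfg1 <- feature_config("cosine_corr", n_harmonics = 1)
  ep_cos <- tone_epoch(signal = cos(2 * pi * 12 * t))
  v <- cosine_corr_features(ep_cos, cfg1)
  expect_equal(unname(v["cc_O1_gabor_h1"]), 1.0, tolerance = 1e-12)

  ep_sin <- tone_epoch(signal = sin(2 * pi * 12 * t))
  v <- cosine_corr_features(ep_sin, cfg1)
  expect_lte(abs(unname(v["cc_O1_gabor_h1"])), 0.02)

  x <- ssvepbci:::with_seed(11, cos(2 * pi * 12 * t) + rnorm(n))
  ep_noisy <- tone_epoch(signal = x)
  v <- cosine_corr_features(ep_noisy, cfg1)
  expect_equal(unname(v["cc_O1_gabor_h1"]),
               pearson_oracle(x, cos(2 * pi * 12 * t)), tolerance = 1e-12)
  expect_true(all(v >= -1 & v <= 1))
})

test_that("a zero-variance channel correlates as 0 with a warning", {
  ep <- tone_epoch(signal = rep(3, FS * 5))
  cfg1 <- feature_config("cosine_corr", 3, channels = "O1")
  expect_warning(v <- cosine_corr_features(ep, cfg1), "zero variance")
  expect_true(all(v == 0))
})

test_that("feature matrices have the combinatorial shape and per-row oracle equality", {
  eps <- sim_baseline_epochs(seed = 21, n_per_condition = 3, duration = 1)
  fm <- assemble_feature_matrix(eps, pb_cfg)
  expect_equal(dim(fm$values), c(6, 3 * 2 * 3))  # channels x tags x harmonics
  expect_identical(fm$trial_index, 1:6)
  for (i in c(1, 4)) {
    expect_equal(fm$values[i, ], extract_features(eps[[i]], pb_cfg))
  }
  # rows ordered by trial_index regardless of input order
  fm2 <- assemble_feature_matrix(rev(eps), pb_cfg)
  expect_equal(fm2$values, fm$values)
  expect_error(assemble_feature_matrix(list(), pb_cfg), "non-empty")
  short <- sim_baseline_epochs(seed = 1, n_per_condition = 1, duration = 2)
  expect_error(assemble_feature_matrix(c(eps, short), pb_cfg), "mixed lengths")
})

test_that("scaling an epoch leaves ratios and correlations unchanged and scales PSD by c^2", {
  ep <- tone_epoch(signal = ssvepbci:::with_seed(13,
    sin(2 * pi * 12 * (0:(FS * 5 - 1)) / FS) + rnorm(FS * 5)))
  scaled <- ep
  scaled$samples <- 2.5 * ep$samples
  expect_equal(power_bank_features(scaled, pb_cfg),
               power_bank_features(ep, pb_cfg), tolerance = 1e-12)
  expect_equal(cosine_corr_features(scaled, cc_cfg),
               cosine_corr_features(ep, cc_cfg), tolerance = 1e-12)
  expect_equal(psd_features(scaled, psd_cfg),
               2.5^2 * psd_features(ep, psd_cfg), tolerance = 1e-9)
})

test_that("missing channels raise an error", {
  m <- matrix(0, 1, FS * 5); rownames(m) <- "CZ"
  ep <- trial_epoch(m, FS, "attend-Gabor", "baseline1", 1L)
  expect_error(psd_features(ep, psd_cfg), "missing from epoch")
})

test_that("mean 12 Hz power-bank feature separates the attention conditions", {
  eps <- sim_baseline_epochs(seed = 31, n_per_condition = 8)
  fm <- assemble_feature_matrix(eps, pb_cfg)
  gabor12 <- rowMeans(fm$values[, grep("gabor_h1", fm$feature_names)])
  face857 <- rowMeans(fm$values[, grep("face_h1", fm$feature_names)])
  is_g <- fm$labels == "attend-Gabor"
  expect_gt(mean(gabor12[is_g]), mean(gabor12[!is_g]))
  expect_gt(mean(face857[!is_g]), mean(face857[is_g]))
})

test_that("feature matrices serialize to CSV + JSON and read back consistently", {
  eps <- sim_baseline_epochs(seed = 41, n_per_condition = 2, duration = 1)
  fm <- assemble_feature_matrix(eps, pb_cfg)
  path <- file.path(tempdir(), "fm")
  write_feature_matrix(fm, path)
  back <- read.csv(paste0(path, ".csv"), check.names = FALSE)
  expect_equal(as.matrix(back[, fm$feature_names]), fm$values,
               ignore_attr = TRUE)
  cfg_back <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(cfg_back$family, "power_bank")
  expect_equal(cfg_back$n_harmonics, 3)
})
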