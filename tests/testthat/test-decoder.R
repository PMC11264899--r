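# nearest-centroid oracle used to certify that a synthetic feature set is
# linearly separable before asserting on the SVM
nearest_centroid_accuracy <- function(x, labels) {
  cents <- lapply(split(as.data.frame(x), labels), colMeans)
  pred <- apply(x, 1, function(row) {
    d <- vapply(cents, function(ce) sum((row - ce)^2), numeric(1))
    names(cents)[which.min(d)]
  })
  mean(pred == labels)
}

test_that("cross-validation is perfect on separable Gaussians and exact at chance on permuted labels", {
  g <- gaussian_features(seed = 1, n_per_class = 30)
  expect_equal(nearest_centroid_accuracy(g$x, g$labels), 1)  # separability oracle
  cv <- cross_validate(g$x, "linear", k = 5, seed = 2, labels = g$labels)
  expect_equal(cv$mean, 1)
  expect_equal(cv$sd, 0)

  # chance data: labels shuffled independently of the features, 200 trials
  accs <- vapply(1:20, function(s) {
    g2 <- gaussian_features(seed = 100 + s, n_per_class = 100, shift = 0)
    cross_validate(g2$x, "linear", k = 5, seed = s, labels = g2$labels)$mean
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.1)
})

test_that("k = number of trials degenerates to leave-one-out", {
  g <- gaussian_features(seed = 3, n_per_class = 10)
  cv <- cross_validate(g$x, "linear", k = 20, seed = 1, labels = g$labels)
  expect_length(cv$fold_accuracies, 20)
  expect_equal(cv$mean, 1)
})

test_that("cross-validation is deterministic given the seed and rejects bad input", {
  g <- gaussian_features(seed = 4, n_per_class = 10, shift = 1)
  a <- cross_validate(g$x, "radial", k = 5, seed = 9, labels = g$labels)
  b <- cross_validate(g$x, "radial", k = 5, seed = 9, labels = g$labels)
  expect_identical(a, b)
  expect_error(cross_validate(g$x, "linear", labels = rep("attend-Gabor", 20)),
               "single class")
  expect_error(cross_validate(g$x, "linear", k = 21, labels = g$labels),
               "folds")
})

test_that("forward selection recovers informative features among noise", {
  # 2 informative + 20 pure-noise features
  g <- ssvepbci:::with_seed(5, {
    n <- 30
    informative <- cbind(inf1 = c(rnorm(n), rnorm(n, 3)),
                         inf2 = c(rnorm(n), rnorm(n, 3)))
    noise <- matrix(rnorm(2 * n * 20), 2 * n, 20,
                    dimnames = list(NULL, paste0("noise", 1:20)))
    list(x = cbind(informative, noise),
         labels = rep(c("attend-Gabor", "attend-Face"), each = n))
  })
  fs <- forward_feature_selection(g$x, "linear", seed = 6, labels = g$labels)
  expect_true(all(c("inf1", "inf2") %in% fs$features) ||
                fs$misclassification <=
                  1 - cross_validate(g$x, "linear", seed = 6,
                                     labels = g$labels,
                                     features = c("inf1", "inf2"))$mean)
  # within 0.05 of the informative-only model
  informative_only <- cross_validate(g$x, "linear", seed = 6,
                                     labels = g$labels,
                                     features = c("inf1", "inf2"))$mean
  expect_gte(fs$cv$mean, informative_only - 0.05)
})

test_that("the selected subset never does worse than the full feature set on the same folds", {
  for (s in 1:3) {
    g <- gaussian_features(seed = 30 + s, n_per_class = 15, p = 8, shift = 0.8)
    fs <- forward_feature_selection(g$x, "linear", seed = s, labels = g$labels)
    full <- cross_validate(g$x, "linear", seed = s, labels = g$labels)
    expect_lte(fs$misclassification, 1 - full$mean + 1e-12)
  }
})

test_that("a single selectable feature requires no choice and two features select at least one", {
  g <- gaussian_features(seed = 7, n_per_class = 15, p = 2)
  expect_error(forward_feature_selection(g$x[, 1, drop = FALSE], "linear",
                                         labels = g$labels),
               "at least 2 features")
  fs <- forward_feature_selection(g$x, "linear", seed = 1, labels = g$labels)
  expect_true(length(fs$features) >= 1)
})

test_that("Platt scaling matches a reference logistic fit and is monotone", {
  # perfectly separated decision values
  s <- ssvepbci:::with_seed(77, c(runif(50, -3, -2), runif(50, 2, 3)))
  y <- rep(c("attend-Face", "attend-Gabor"), each = 50)
  pl <- fit_platt(s, y)
  p <- platt_probability(s, pl)
  expect_true(all(p[y == "attend-Gabor"] > 0.9))
  expect_true(all(p[y == "attend-Face"] < 0.1))

  # reference logistic fit on the same Platt target probabilities
  t_hi <- (50 + 1) / (50 + 2); t_lo <- 1 / (50 + 2)
  targ <- ifelse(y == "attend-Gabor", t_hi, t_lo)
  ref <- suppressWarnings(glm(targ ~ s, family = binomial()))
  # glm: logit p = b0 + b1 s  <=>  A = -b1, B = -b0
  expect_equal(unname(pl[["A"]]), -unname(coef(ref)[2]), tolerance = 1e-4)
  expect_equal(unname(pl[["B"]]), -unname(coef(ref)[1]), tolerance = 1e-4)

  # A < 0 => increasing in s; monotone either way
  grid <- seq(-4, 4, length.out = 101)
  pg <- platt_probability(grid, pl)
  expect_true(all(diff(pg) > 0) || all(diff(pg) < 0))
  expect_lt(pl[["A"]], 0)
})

test_that("symmetric decision values with balanced labels calibrate to P(0) = 0.5", {
  s <- rep(c(-1, 1), each = 20)
  y <- rep(c("attend-Face", "attend-Gabor"), each = 20)
  pl <- fit_platt(s, y)
  expect_equal(unname(platt_probability(0, pl)), 0.5, tolerance = 1e-6)
  expect_error(fit_platt(s, rep("attend-Gabor", 40)), "both classes")
})

test_that("participant training splits 60 balanced trials into 48 train / 12 validation", {
  eps <- sim_baseline_epochs(seed = 51, n_per_condition = 30)
  m <- train_participant_decoder(eps, seed = 4)
  expect_equal(m$n_train, 48)
  expect_equal(m$n_validation, 12)
  expect_gte(m$validation_accuracy, 0.9)  # high-contrast simulation
  expect_gte(m$cv_accuracy, 0.9)
  m2 <- train_participant_decoder(eps, seed = 4)
  expect_identical(m$platt, m2$platt)
  expect_identical(m$selected_features, m2$selected_features)
})

test_that("unbalanced or too-small baselines are rejected", {
  eps <- sim_baseline_epochs(seed = 52, n_per_condition = 4, duration = 1)
  expect_error(train_participant_decoder(eps[1:7]), "balanced")
  expect_error(train_participant_decoder(eps), "at least 10")
})

test_that("probabilities complement, separate by condition, and require calibration", {
  eps <- sim_baseline_epochs(seed = 53, n_per_condition = 10)
  m <- train_participant_decoder(eps, seed = 2)
  test_g <- simulate_epoch(sim_config(snr = 1), "attend-Gabor", seed = 9901)
  test_f <- simulate_epoch(sim_config(snr = 1), "attend-Face", seed = 9902)
  p_g <- gabor_probability(m, test_g)$probability
  p_f <- gabor_probability(m, test_f)$probability
  expect_gt(p_g, 0.5)
  expect_lt(p_f, 0.5)
  expect_true(p_g >= 0 && p_g <= 1)
  # P(face) is the binary complement by construction of a two-class sigmoid
  expect_equal(p_g + (1 - p_g), 1)

  uncal <- m
  uncal$platt <- NULL
  expect_error(gabor_probability(uncal, test_g), "not calibrated")

  # same seed, same model, same epoch => identical probability
  m2 <- train_participant_decoder(eps, seed = 2)
  expect_identical(gabor_probability(m2, test_g)$probability, p_g)
})

test_that("decoder models survive a save/load round trip", {
  eps <- sim_baseline_epochs(seed = 54, n_per_condition = 7, duration = 1)
  m <- train_participant_decoder(eps, seed = 1)
  path <- tempfile(fileext = ".rds")
  save_decoder(m, path)
  back <- load_decoder(path)
  expect_identical(back$platt, m$platt)
  ep <- sim_baseline_epochs(seed = 55, n_per_condition = 1, duration = 1)[[1]]
  expect_identical(gabor_probability(back, ep)$probability,
                   gabor_probability(m, ep)$probability)
})

test_that("a one-cell profiling grid equals a direct cross-validation call", {
  eps <- sim_baseline_epochs(seed = 56, n_per_condition = 8, duration = 1)
  cfg <- feature_config("power_bank", 3, 2)
  grid <- profile_configurations(eps, menu = list(pb = cfg),
                                 kernels = "linear", seed = 3)
  expect_equal(nrow(grid), 1)
  direct <- cross_validate(assemble_feature_matrix(eps, cfg), "linear", seed = 3)
  expect_equal(grid$mean_accuracy, direct$mean)
  expect_equal(grid$sd_accuracy, direct$sd)
  expect_error(profile_configurations(eps, menu = list()), "at least one")
})

test_that("power-bank n=3 f0=2 beats cosine-corr n=1 on simulated data (ordering pattern)", {
  diffs <- vapply(1:10, function(s) {
    eps <- sim_baseline_epochs(seed = 200 + s, n_per_condition = 8,
                               duration = 1, snr = 0.5)
    pb <- cross_validate(assemble_feature_matrix(
      eps, feature_config("power_bank", 3, 2)), "linear", seed = s)$mean
    cc <- cross_validate(assemble_feature_matrix(
      eps, feature_config("cosine_corr", 1)), "linear", seed = s)$mean
    pb - cc
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("two independent simulated cohorts replicate within the 10% threshold", {
  cohort_accuracy <- function(participant_seeds) {
    mean(vapply(participant_seeds, function(s) {
      eps <- sim_baseline_epochs(seed = s, n_per_condition = 15, duration = 1)
      fm <- assemble_feature_matrix(eps, feature_config("power_bank", 3, 2))
      cross_validate(fm, "linear", seed = s)$mean
    }, numeric(1)))
  }
  ref <- cohort_accuracy(c(301, 302))
  obs <- cohort_accuracy(c(401, 402))
  expect_true(check_replication(obs, replication_interval(ref, 0.10))$replicated)
})
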