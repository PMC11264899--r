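POSITIVE_CLASS <- "attend-Gabor"
KERNELS <- c("linear", "polynomial", "radial")

# Fit an e1071 SVM with the package's fixed hyperparameters: C = 1,
# polynomial degree 3 with coef0 = 1, RBF/poly gamma = 1/(p * var(X))
# (falling back to 1/p for constant matrices). Features are used unscaled:
# power-bank ratios and correlations are already bounded.
fit_svm <- function(x, y, kernel) {
  kernel <- match.arg(kernel, KERNELS)
  p <- ncol(x)
  v <- var(as.vector(x))
  gamma <- if (is.finite(v) && v > 0) 1 / (p * v) else 1 / p
  e1071::svm(x = x, y = y, kernel = kernel, cost = 1, degree = 3, coef0 = 1,
             gamma = gamma, scale = FALSE)
}

# Signed decision values for an e1071 SVM, oriented so positive favours the
# model's first factor level. Orientation is irrelevant downstream because
# Platt scaling is fitted on these same values.
decision_values <- function(fit, x) {
  as.numeric(attr(predict(fit, x, decision.values = TRUE), "decision.values"))
}

as_label_factor <- function(labels) {
  factor(labels, levels = c(POSITIVE_CLASS, setdiff(unique(labels), POSITIVE_CLASS)))
}

# Seeded stratified fold assignment: within each class, indices are shuffled
# and dealt round-robin over folds.
stratified_folds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- sample(which(labels == cls))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Stratified k-fold cross-validated decoding accuracy
#'
#' Fits the SVM on k-1 folds and scores the held-out fold, for each of `k`
#' seeded stratified folds. With `k` equal to the number of trials this
#' degenerates to leave-one-out.
#'
#' @param X A [assemble_feature_matrix()] result, or a plain numeric matrix
#'   (then `labels` must be given).
#' @param kernel `"linear"`, `"polynomial"` or `"radial"`.
#' @param k Number of folds.
#' @param seed Integer seed for the fold assignment.
#' @param labels Per-trial labels when `X` is a plain matrix.
#' @param features Optional subset of feature names (or column indices) to use.
#' @return List with `mean`, `sd` and `fold_accuracies`.
#' @export
cross_validate <- function(X, kernel = "linear", k = 5, seed = 1,
                           labels = NULL, features = NULL) {
  if (inherits(X, "feature_matrix")) {
    labels <- X$labels
    X <- X$values
  }
  abort_if(is.null(labels), "`labels` required when `X` is a plain matrix")
  y <- as_label_factor(labels)
  abort_if(nlevels(droplevels(y)) < 2L, "labels contain a single class")
  counts <- table(y)
  abort_if(any(counts < k) && k < length(y),
           "need at least k = ", k, " trials per class for stratified folds")
  abort_if(k > length(y), "more folds than trials")
  if (!is.null(features)) X <- X[, features, drop = FALSE]
  folds <- if (k == length(y)) seq_len(length(y))
           else stratified_folds(as.character(y), k, seed)
  acc <- vapply(seq_len(k), function(fold) {
    test <- folds == fold
    fit <- fit_svm(X[!test, , drop = FALSE], droplevels(y[!test]), kernel)
    pred <- predict(fit, X[test, , drop = FALSE])
    mean(as.character(pred) == as.character(y[test]))
  }, numeric(1))
  list(mean = mean(acc), sd = sd(acc), fold_accuracies = acc)
}

#' Greedy forward feature selection by cross-validated misclassification
#'
#' Grows a feature bank from empty: at each step every remaining candidate
#' (visited in a seeded random order) is scored by the k-fold cross-validated
#' misclassification of the bank plus that candidate, on one fixed seeded
#' fold assignment; the best candidate (ties broken by lowest feature index)
#' is added while it improves the bank's misclassification, and the loop
#' stops at the first non-improving step. The full feature set is also scored
#' on the same folds, and the subset returned is the best configuration
#' observed, so the selection never does worse than using all features.
#'
#' @inheritParams cross_validate
#' @return List with `features` (selected names), `misclassification`,
#'   `cv` (the [cross_validate()] result of the selected subset) and `path`
#'   (data frame of the greedy trajectory).
#' @export
forward_feature_selection <- function(X, kernel = "linear", k = 5, seed = 1,
                                      labels = NULL) {
  if (inherits(X, "feature_matrix")) {
    labels <- X$labels
    X <- X$values
  }
  abort_if(ncol(X) < 2L, "need at least 2 features to select from")
  p <- ncol(X)
  nm <- colnames(X)
  if (is.null(nm)) nm <- colnames(X) <- paste0("f", seq_len(p))
  cv_err <- function(feat) 1 - cross_validate(X, kernel, k, seed,
                                              labels = labels,
                                              features = feat)$mean
  full_err <- cv_err(seq_len(p))
  order_visit <- with_seed(seed, sample.int(p))
  bank <- integer(0)
  bank_err <- Inf
  path <- list()
  repeat {
    remaining <- setdiff(order_visit, bank)
    if (length(remaining) == 0L) break
    errs <- vapply(remaining, function(j) cv_err(c(bank, j)), numeric(1))
    best <- min(errs)
    cand <- remaining[errs == best]
    pick <- min(cand)  # tie-break: lowest feature index
    if (best < bank_err) {
      bank <- c(bank, pick)
      bank_err <- best
      path[[length(path) + 1L]] <- data.frame(feature = nm[pick],
                                              misclassification = best)
    } else break
  }
  if (full_err < bank_err) {
    bank <- seq_len(p)
    bank_err <- full_err
  }
  sel <- nm[bank]
  list(features = sel, misclassification = bank_err,
       cv = cross_validate(X, kernel, k, seed, labels = labels,
                           features = sel),
       path = do.call(rbind, path))
}

#' Fit Platt's sigmoid to decision values
#'
#' Maximum-likelihood fit of `P(y = +1 | s) = 1 / (1 + exp(A*s + B))` to
#' classifier decision values, with Platt's regularized target
#' probabilities `(N+ + 1)/(N+ + 2)` and `1/(N- + 2)` in place of hard 0/1
#' labels. Uses the numerically stable Newton iteration with backtracking
#' line search.
#'
#' @param decision_values Numeric vector of raw classifier scores.
#' @param labels Per-case labels; `positive` names the positive class.
#' @param positive Label treated as the positive class.
#' @return Named vector `c(A, B)`.
#' @export
fit_platt <- function(decision_values, labels, positive = POSITIVE_CLASS) {
  y <- labels == positive
  abort_if(!any(y) || all(y),
           "calibration set must contain both classes")
  n_pos <- sum(y)
  n_neg <- sum(!y)
  hi <- (n_pos + 1) / (n_pos + 2)
  lo <- 1 / (n_neg + 2)
  t <- ifelse(y, hi, lo)
  s <- decision_values

  fval <- function(A, B) {
    f <- A * s + B
    # stable cross-entropy: t*f + log(1 + exp(-f)) for f >= 0, else
    # (t-1)*f + log(1 + exp(f))
    sum(ifelse(f >= 0, t * f + log1p(exp(-f)), (t - 1) * f + log1p(exp(f))))
  }
  A <- 0
  B <- log((n_neg + 1) / (n_pos + 1))
  fv <- fval(A, B)
  sigma_min <- 1e-12
  for (it in 1:100) {
    f <- A * s + B
    p <- ifelse(f >= 0, exp(-f) / (1 + exp(-f)), 1 / (1 + exp(f)))
    q <- 1 - p
    d1 <- p * q
    # gradient and Hessian of the negative log-likelihood in (A, B)
    g1 <- sum(s * (t - p))
    g2 <- sum(t - p)
    if (abs(g1) < 1e-10 && abs(g2) < 1e-10) break
    h11 <- sum(s * s * d1) + sigma_min
    h22 <- sum(d1) + sigma_min
    h21 <- sum(s * d1)
    det <- h11 * h22 - h21 * h21
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    # gradient here is of +loglik in t - p form; descend on fval
    gd <- g1 * dA + g2 * dB
    step <- 1
    repeat {
      newA <- A + step * dA
      newB <- B + step * dB
      newf <- fval(newA, newB)
      if (newf < fv + 1e-4 * step * gd || step < 1e-10) break
      step <- step / 2
    }
    if (step < 1e-10) break
    A <- A + step * dA
    B <- B + step * dB
    fv <- fval(A, B)
  }
  c(A = A, B = B)
}

#' Calibrated probability from a Platt sigmoid
#'
#' @param s Decision value(s).
#' @param platt Coefficients from [fit_platt()].
#' @return `1 / (1 + exp(A*s + B))`, clamped to (0, 1) by construction.
#' @export
platt_probability <- function(s, platt) {
  f <- platt[["A"]] * s + platt[["B"]]
  ifelse(f >= 0, exp(-f) / (1 + exp(-f)), 1 / (1 + exp(f)))
}

#' Train a participant-specific calibrated decoder
#'
#' Implements the participant-specific training recipe: a seeded stratified
#' 80/20 split of the baseline trials, SVM fitted on the 80% (after forward
#' feature selection when the configuration asks for it), Platt sigmoid
#' fitted on the 20% validation decision values, and 5-fold cross-validated
#' accuracy recorded from the training portion.
#'
#' @param baseline_epochs List of labeled baseline [trial_epoch()]s
#'   (balanced, at least 5 per condition), or a ready `feature_matrix`.
#' @param cfg A [feature_config()] (ignored when a feature matrix is given).
#' @param kernel SVM kernel.
#' @param seed Integer seed controlling the split, folds and selection order.
#' @return An object of class `decoder_model`.
#' @export
train_participant_decoder <- function(baseline_epochs,
                                      cfg = feature_config("power_bank",
                                                           n_harmonics = 3,
                                                           f0 = 2),
                                      kernel = "linear", seed = 1) {
  fm <- if (inherits(baseline_epochs, "feature_matrix")) baseline_epochs
        else assemble_feature_matrix(baseline_epochs, cfg)
  cfg <- fm$config
  y <- as_label_factor(fm$labels)
  counts <- table(as.character(y))
  abort_if(length(counts) != 2L, "baseline must contain both conditions")
  abort_if(counts[1] != counts[2], "baseline classes must be balanced (",
           paste(counts, collapse = " vs "), ")")
  abort_if(sum(counts) < 10L, "need at least 10 balanced baseline trials")

  # stratified 80/20: per class, a seeded shuffle; first 80% train
  idx_train <- with_seed(seed, {
    unlist(lapply(unique(as.character(y)), function(cls) {
      idx <- sample(which(y == cls))
      idx[seq_len(round(0.8 * length(idx)))]
    }))
  })
  idx_val <- setdiff(seq_along(y), idx_train)

  Xtr <- fm$values[idx_train, , drop = FALSE]
  ytr <- fm$labels[idx_train]
  sel <- fm$feature_names
  fs_result <- NULL
  if (cfg$use_feature_selection) {
    fs_result <- forward_feature_selection(Xtr, kernel, k = 5, seed = seed,
                                           labels = ytr)
    sel <- fs_result$features
  }
  cv <- cross_validate(Xtr, kernel, k = 5, seed = seed, labels = ytr,
                       features = sel)
  fit <- fit_svm(Xtr[, sel, drop = FALSE], as_label_factor(ytr), kernel)
  sv <- decision_values(fit, fm$values[idx_val, sel, drop = FALSE])
  platt <- fit_platt(sv, fm$labels[idx_val])
  val_prob <- platt_probability(sv, platt)
  val_acc <- mean((val_prob > 0.5) == (fm$labels[idx_val] == POSITIVE_CLASS))

  structure(list(fit = fit, kernel = kernel,
                 hyperparameters = list(cost = 1, degree = 3, coef0 = 1,
                                        gamma = fit$gamma),
                 config = cfg, selected_features = sel,
                 feature_selection = fs_result,
                 platt = platt, cv_accuracy = cv$mean, cv_sd = cv$sd,
                 validation_accuracy = val_acc,
                 n_train = length(idx_train), n_validation = length(idx_val),
                 n_samples_epoch = NULL, positive_class = POSITIVE_CLASS,
                 seed = seed),
            class = "decoder_model")
}

#' @export
print.decoder_model <- function(x, ...) {
  cat(sprintf(paste0("<decoder_model> %s SVM on %d %s features | ",
                     "CV %.3f +/- %.3f | validation %.3f | Platt A=%.3f B=%.3f\n"),
              x$kernel, length(x$selected_features), x$config$family,
              x$cv_accuracy, x$cv_sd, x$validation_accuracy,
              x$platt[["A"]], x$platt[["B"]]))
  invisible(x)
}

#' Calibrated probability that attention was on the Gabor
#'
#' Featurizes the epoch with the model's configuration, evaluates the SVM
#' decision value and maps it through the model's Platt sigmoid. Scores above
#' 0.5 mean the Gabor "won" the attentional competition on that trial.
#'
#' @param model A trained [train_participant_decoder()] model.
#' @param epoch A [trial_epoch()].
#' @return One-row data frame of class `feedback_score`: `trial_index`,
#'   `face_id`, `epoch_number`, `exposure_count`, `probability`.
#' @export
gabor_probability <- function(model, epoch) {
  abort_if(!inherits(model, "decoder_model"), "`model` must be a decoder_model")
  abort_if(is.null(model$platt), "model is not calibrated: no Platt coefficients")
  v <- extract_features(epoch, model$config)
  x <- matrix(v[model$selected_features], nrow = 1,
              dimnames = list(NULL, model$selected_features))
  s <- decision_values(model$fit, x)
  p <- unname(platt_probability(s, model$platt))
  structure(data.frame(trial_index = epoch$trial_index,
                       face_id = epoch$face_id,
                       epoch_number = epoch$epoch_number,
                       exposure_count = epoch$exposure_count,
                       probability = p),
            class = c("feedback_score", "data.frame"))
}

#' The standard 14-configuration feature menu
#'
#' PSD with and without forward selection; power banks over
#' `n_harmonics` 1-3 and `f0` 1.5 / 2 Hz (with forward selection at n = 3);
#' cosine correlations over `n_harmonics` 1-3 (with forward selection at
#' n = 3). Crossed with the three kernels this yields the full 42-cell
#' profiling grid.
#'
#' @return Named list of [feature_config()]s.
#' @export
default_feature_menu <- function() {
  menu <- list(
    "PSD" = feature_config("psd"),
    "PSD, FS" = feature_config("psd", use_feature_selection = TRUE),
    "Power bank, n=1, f0=1.5" = feature_config("power_bank", 1, 1.5),
    "Power bank, n=2, f0=1.5" = feature_config("power_bank", 2, 1.5),
    "Power bank, n=3, f0=1.5" = feature_config("power_bank", 3, 1.5),
    "Power bank, n=3, f0=1.5, FS" = feature_config("power_bank", 3, 1.5,
                                                   use_feature_selection = TRUE),
    "Power bank, n=1, f0=2" = feature_config("power_bank", 1, 2),
    "Power bank, n=2, f0=2" = feature_config("power_bank", 2, 2),
    "Power bank, n=3, f0=2" = feature_config("power_bank", 3, 2),
    "Power bank, n=3, f0=2, FS" = feature_config("power_bank", 3, 2,
                                                 use_feature_selection = TRUE),
    "Cosine corr, n=1" = feature_config("cosine_corr", 1),
    "Cosine corr, n=2" = feature_config("cosine_corr", 2),
    "Cosine corr, n=3" = feature_config("cosine_corr", 3),
    "Cosine corr, n=3, FS" = feature_config("cosine_corr", 3,
                                            use_feature_selection = TRUE))
  menu
}

#' Profile feature configurations against kernels
#'
#' Runs seeded 5-fold cross-validation (with forward feature selection first,
#' where a configuration asks for it) for every feature configuration x
#' kernel cell and records mean and SD of the fold accuracies plus wall-clock
#' training time.
#'
#' @param epochs List of labeled baseline [trial_epoch()]s.
#' @param menu Named list of [feature_config()]s
#'   (default [default_feature_menu()]).
#' @param kernels Character vector of SVM kernels.
#' @param seed Integer seed.
#' @param k Folds.
#' @return A `profiling_grid` data frame: configuration, kernel,
#'   mean_accuracy, sd_accuracy, n_features, train_time_s.
#' @export
profile_configurations <- function(epochs, menu = default_feature_menu(),
                                   kernels = KERNELS, seed = 1, k = 5) {
  abort_if(length(menu) == 0L, "`menu` must contain at least one configuration")
  abort_if(length(kernels) == 0L, "`kernels` must be non-empty")
  rows <- list()
  for (cfg_name in names(menu)) {
    cfg <- menu[[cfg_name]]
    fm <- assemble_feature_matrix(epochs, cfg)
    for (kernel in kernels) {
      t0 <- proc.time()[["elapsed"]]
      if (cfg$use_feature_selection) {
        fs <- forward_feature_selection(fm, kernel, k = k, seed = seed)
        cv <- fs$cv
        nf <- length(fs$features)
      } else {
        cv <- cross_validate(fm, kernel, k = k, seed = seed)
        nf <- ncol(fm$values)
      }
      rows[[length(rows) + 1L]] <-
        data.frame(configuration = cfg_name, kernel = kernel,
                   mean_accuracy = cv$mean, sd_accuracy = cv$sd,
                   n_features = nf,
                   train_time_s = proc.time()[["elapsed"]] - t0)
    }
  }
  grid <- do.call(rbind, rows)
  class(grid) <- c("profiling_grid", "data.frame")
  grid
}

#' Select the best profiling cell
#'
#' Highest mean accuracy; optionally restricted to configurations without
#' forward feature selection, the constraint used when selection runtime
#' would delay a same-session protocol.
#'
#' @param grid A [profile_configurations()] result.
#' @param exclude_fs Drop forward-feature-selection rows before selecting.
#' @return The selected row of the grid.
#' @export
select_best_configuration <- function(grid, exclude_fs = FALSE) {
  g <- grid
  if (exclude_fs) g <- g[!grepl("FS", g$configuration), , drop = FALSE]
  abort_if(nrow(g) == 0L, "no eligible configurations")
  g[which.max(g$mean_accuracy), , drop = FALSE]
}

#' Reshape a profiling grid to the wide feature-by-kernel table
#'
#' One row per feature configuration, one `mean +/- sd` column per kernel —
#' the layout used to report profiling results.
#'
#' @param grid A [profile_configurations()] result.
#' @param digits Rounding for display.
#' @return Data frame with columns `configuration` and one per kernel.
#' @export
format_profiling_grid <- function(grid, digits = 3) {
  cfgs <- unique(grid$configuration)
  kernels <- unique(grid$kernel)
  out <- data.frame(configuration = cfgs, stringsAsFactors = FALSE)
  for (kn in kernels) {
    out[[kn]] <- vapply(cfgs, function(cf) {
      row <- grid[grid$configuration == cf & grid$kernel == kn, ]
      sprintf("%.*f ± %.*f", digits, row$mean_accuracy[1],
              digits, row$sd_accuracy[1])
    }, character(1))
  }
  out
}

#' Save / load a decoder model bundle
#'
#' Single-file R-native serialization of the full model state (fitted SVM,
#' configuration, selected features, Platt coefficients, accuracies).
#'
#' @param model A `decoder_model`.
#' @param path File path.
#' @return `path` invisibly; `load_decoder` returns the model.
#' @export
save_decoder <- function(model, path) {
  abort_if(!inherits(model, "decoder_model"), "`model` must be a decoder_model")
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_decoder
#' @export
load_decoder <- function(path) {
  model <- readRDS(path)
  abort_if(!inherits(model, "decoder_model"), path, " does not hold a decoder_model")
  model
}
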