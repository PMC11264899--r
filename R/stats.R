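#' Guttman split-half reliability of trial scores
#'
#' Splits each unit's trial scores into odd and even presentation positions,
#' aggregates each half per unit (mean by default), and returns Guttman's
#' split-half coefficient
#' `lambda4 = 2 * (1 - (V_odd + V_even) / V_total)`, where the variances are
#' taken across units and `V_total` is the variance of the summed half-scores.
#' A coefficient near 1 means the two halves carry the same between-unit
#' signal, i.e. internally consistent feedback.
#'
#' @param scores Data frame with a numeric `score` column (or `probability`,
#'   used as fallback), a `unit` column (e.g. participant), and trials ordered
#'   by presentation within unit.
#' @param aggregate Per-half aggregation, `"mean"` or `"sum"`.
#' @return An object of class `reliability_report`: `guttman_coefficient`,
#'   `n_units`, `n_trials_odd`, `n_trials_even`.
#' @export
#' @examples
#' d <- data.frame(unit = rep(1:5, each = 4),
#'                 score = rep(c(.2, .4, .6, .8, .5), each = 4))
#' guttman_split_half(d)$guttman_coefficient  # parallel halves: exactly 1
guttman_split_half <- function(scores, aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  abort_if(!is.data.frame(scores), "`scores` must be a data frame")
  if (is.null(scores$score)) scores$score <- scores$probability
  abort_if(is.null(scores$score), "`scores` needs a `score` column")
  if (is.null(scores$unit)) scores$unit <- scores$participant
  abort_if(is.null(scores$unit), "`scores` needs a `unit` column")
  abort_if(nrow(scores) < 4L, "need at least 4 trials")
  agg <- match.fun(aggregate)
  halves <- lapply(split(scores$score, scores$unit), function(x) {
    odd <- x[seq_along(x) %% 2 == 1]
    even <- x[seq_along(x) %% 2 == 0]
    c(odd = agg(odd), even = agg(even), n_odd = length(odd),
      n_even = length(even))
  })
  h <- do.call(rbind, halves)
  abort_if(nrow(h) < 2L, "need at least 2 units to take variances across units")
  v_odd <- var(h[, "odd"])
  v_even <- var(h[, "even"])
  v_total <- var(h[, "odd"] + h[, "even"])
  abort_if(v_total == 0,
           "total variance of half-scores is zero; coefficient undefined")
  structure(list(guttman_coefficient = 2 * (1 - (v_odd + v_even) / v_total),
                 n_units = nrow(h),
                 n_trials_odd = sum(h[, "n_odd"]),
                 n_trials_even = sum(h[, "n_even"]),
                 aggregate = aggregate),
            class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf("<reliability_report> Guttman lambda4 = %.3f (%d units, %d odd / %d even trials)\n",
              x$guttman_coefficient, x$n_units, x$n_trials_odd, x$n_trials_even))
  invisible(x)
}

#' Relative replication-threshold interval
#'
#' The acceptance band for replicating a reference decoding accuracy:
#' `[reference * (1 - tolerance), reference * (1 + tolerance)]`. With the
#' standard 10% tolerance, a reference accuracy of 0.770 gives the band
#' (0.693, 0.847).
#'
#' @param reference Reference accuracy fraction in (0, 1].
#' @param tolerance Relative tolerance in [0, 1).
#' @return List with `lo`, `hi`, `reference`, `tolerance`.
#' @export
#' @examples
#' replication_interval(0.770)  # (0.693, 0.847)
replication_interval <- function(reference, tolerance = 0.10) {
  abort_if(!(reference > 0 && reference <= 1), "`reference` must be in (0, 1]")
  abort_if(!(tolerance >= 0 && tolerance < 1), "`tolerance` must be in [0, 1)")
  list(lo = reference * (1 - tolerance), hi = reference * (1 + tolerance),
       reference = reference, tolerance = tolerance)
}

#' Classify an observed accuracy against a replication interval
#'
#' @param observed Observed accuracy fraction.
#' @param interval A [replication_interval()] (or a bare reference accuracy,
#'   in which case the default 10% tolerance is applied).
#' @return An object of class `replication_decision` with fields
#'   `reference_accuracy`, `tolerance`, `interval`, `observed_accuracy`,
#'   `replicated`.
#' @export
#' @examples
#' check_replication(0.710, replication_interval(0.770))$replicated
check_replication <- function(observed, interval) {
  if (is.numeric(interval)) interval <- replication_interval(interval)
  structure(list(reference_accuracy = interval$reference,
                 tolerance = interval$tolerance,
                 interval = c(lo = interval$lo, hi = interval$hi),
                 observed_accuracy = observed,
                 replicated = observed >= interval$lo & observed <= interval$hi),
            class = "replication_decision")
}

#' @export
print.replication_decision <- function(x, ...) {
  cat(sprintf("<replication_decision> observed %.3f vs (%.3f, %.3f): %s\n",
              x$observed_accuracy, x$interval[["lo"]], x$interval[["hi"]],
              if (x$replicated) "replicated" else "not replicated"))
  invisible(x)
}

#' Paired t-test with the paired effect size dz
#'
#' Two-sided paired t-test between matched per-unit means, returning the
#' paired Cohen's `dz = t / sqrt(n)` alongside the test.
#'
#' @param a,b Numeric vectors of equal length >= 2 (e.g. per-participant mean
#'   probabilities under two instructions).
#' @return An `effect_report` list: `t`, `df`, `p`, `dz`, `n`, `mean_a`,
#'   `sd_a`, `mean_b`, `sd_b`.
#' @export
paired_t <- function(a, b) {
  abort_if(length(a) != length(b), "`a` and `b` must be matched (equal length)")
  abort_if(length(a) < 2L, "need at least 2 paired units")
  n <- length(a)
  dif <- a - b
  if (sd(dif) == 0) {
    # constant differences: t is 0 for identical vectors, +/-Inf otherwise
    tval <- if (mean(dif) == 0) 0 else sign(mean(dif)) * Inf
    ht <- list(statistic = tval, parameter = n - 1,
               p.value = if (tval == 0) 1 else 0)
  } else {
    ht <- t.test(a, b, paired = TRUE)
  }
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, dz = unname(ht$statistic) / sqrt(n), n = n,
                 mean_a = mean(a), sd_a = sd(a),
                 mean_b = mean(b), sd_b = sd(b)),
            class = "effect_report")
}

#' @export
print.effect_report <- function(x, ...) {
  if (!is.null(x$t))
    cat(sprintf("t(%g) = %.3f, p = %.3f, dz = %.3f\n", x$df, x$t, x$p, x$dz))
  if (!is.null(x$effects)) print(x$effects)
  invisible(x)
}

#' Partial eta squared from an F statistic
#'
#' `F * df1 / (F * df1 + df2)`, the effect-size measure reported for
#' within-subject ANOVA effects.
#'
#' @param f F statistic.
#' @param df1,df2 Numerator and denominator degrees of freedom.
#' @return Partial eta squared in [0, 1].
#' @export
#' @examples
#' partial_eta_sq(2.135, 1, 4)  # 0.348
partial_eta_sq <- function(f, df1, df2) f * df1 / (f * df1 + df2)

#' Two-way repeated-measures ANOVA on feedback probabilities
#'
#' Classical univariate within-subject decomposition for a complete
#' Time (first vs second half of the feedback phase) x Trial (face exposure
#' 1-5) design with participants as the repeated factor, fitted with
#' [stats::aov()] error strata; no sphericity correction is applied. Each
#' effect is reported with its F, design degrees of freedom, p, and partial
#' eta squared.
#'
#' @param cells Data frame with columns `participant`, `time` (2 levels),
#'   `trial` (5 levels) and `probability`, one row per cell per participant.
#' @return An `effect_report` whose `effects` element is a data frame with
#'   rows Time, Trial and Time:Trial.
#' @export
rm_anova_2x5 <- function(cells) {
  need <- c("participant", "time", "trial", "probability")
  abort_if(!all(need %in% names(cells)),
           "`cells` needs columns ", paste(need, collapse = ", "))
  d <- data.frame(participant = factor(cells$participant),
                  time = factor(cells$time), trial = factor(cells$trial),
                  probability = cells$probability)
  tab <- table(d$participant, d$time, d$trial)
  abort_if(any(tab != 1L),
           "design must be complete: one value per participant x time x trial cell")
  fit <- aov(probability ~ time * trial + Error(participant / (time * trial)),
             data = d)
  sm <- summary(fit)
  pull <- function(stratum, term) {
    tb <- sm[[stratum]][[1]]
    i <- match(term, trimws(rownames(tb)))
    resid <- nrow(tb)
    data.frame(effect = sub(":", " x ", term),
               F = tb[i, "F value"], df1 = tb[i, "Df"], df2 = tb[resid, "Df"],
               p = tb[i, "Pr(>F)"],
               eta_p_sq = partial_eta_sq(tb[i, "F value"], tb[i, "Df"],
                                         tb[resid, "Df"]))
  }
  effects <- rbind(pull("Error: participant:time", "time"),
                   pull("Error: participant:trial", "trial"),
                   pull("Error: participant:time:trial", "time:trial"))
  rownames(effects) <- NULL
  structure(list(effects = effects), class = "effect_report")
}

#' Correlate feedback performance with acceptability responses
#'
#' Pearson correlation (with its two-sided p) between per-participant average
#' Gabor probabilities and each questionnaire item. Items with zero variance
#' (or zero variance in the probabilities) are reported as `NA` with a note
#' rather than an error.
#'
#' @param avg_probabilities Named (or ordered) numeric vector, one value per
#'   participant.
#' @param questionnaire Data frame, one row per participant (matched order),
#'   one numeric column per item (e.g. the seven acceptability items on a
#'   1-5 scale).
#' @return Data frame: `item`, `r`, `p`, `n`, `note`.
#' @export
acceptability_correlations <- function(avg_probabilities, questionnaire) {
  abort_if(length(avg_probabilities) != nrow(questionnaire),
           "participant sets must match")
  abort_if(length(avg_probabilities) < 3L, "need at least 3 participants")
  rows <- lapply(names(questionnaire), function(item) {
    y <- questionnaire[[item]]
    if (var(avg_probabilities) == 0 || var(y) == 0) {
      data.frame(item = item, r = NA_real_, p = NA_real_,
                 n = length(y), note = "zero variance")
    } else {
      ct <- cor.test(avg_probabilities, y)
      data.frame(item = item, r = unname(ct$estimate), p = ct$p.value,
                 n = length(y), note = "")
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
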