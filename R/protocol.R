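FACE_POOL <- as.vector(outer(sprintf("actor%02d", 1:15), c("sad", "angry"),
                             paste, sep = "_"))

#' Build a session schedule
#'
#' The session comprises two instructed baseline phases and an optional
#' neurofeedback phase. Baseline 1 is 30 attend-Gabor trials and baseline 2 is
#' 30 attend-Face trials, each running through the 30-face pool (15 actors x
#' sad/angry) in a seeded random order. The feedback phase has 3 epochs of 50
#' trials; within an epoch 10 faces are drawn without replacement from the
#' pool and each is shown for 5 consecutive trials (`exposure_count` 1-5),
#' with face order randomly permuted per phase under the seed.
#'
#' @param seed Integer seed controlling all face permutations.
#' @param include_feedback Include the 150-trial feedback phase.
#' @return A `session_schedule` data frame: `trial_index`, `phase`,
#'   `condition`, `face_id`, `epoch_number`, `exposure_count`.
#' @export
#' @examples
#' sched <- build_schedule(seed = 42)
#' table(sched$phase)
build_schedule <- function(seed = 1, include_feedback = TRUE) {
  rows <- with_seed(seed, {
    b1 <- data.frame(phase = "baseline1", condition = "attend-Gabor",
                     face_id = sample(FACE_POOL, 30),
                     epoch_number = NA_integer_, exposure_count = 1L)
    b2 <- data.frame(phase = "baseline2", condition = "attend-Face",
                     face_id = sample(FACE_POOL, 30),
                     epoch_number = NA_integer_, exposure_count = 1L)
    out <- rbind(b1, b2)
    if (include_feedback) {
      for (ep in 1:3) {
        faces <- sample(FACE_POOL, 10)  # 10 faces per epoch, run of 5 each
        fb <- data.frame(phase = "feedback", condition = "feedback",
                         face_id = rep(faces, each = 5),
                         epoch_number = ep,
                         exposure_count = rep(1:5, times = 10))
        out <- rbind(out, fb)
      }
    }
    out
  })
  rows$trial_index <- seq_len(nrow(rows))
  rows <- rows[, c("trial_index", "phase", "condition", "face_id",
                   "epoch_number", "exposure_count")]
  class(rows) <- c("session_schedule", "data.frame")
  rows
}

#' Validate session schedule invariants
#'
#' Checks the structural contract: 30 attend-Gabor trials in baseline 1,
#' 30 attend-Face trials in baseline 2, 3 feedback epochs of exactly 50
#' trials, 10 distinct faces per feedback epoch each shown in a run of 5
#' consecutive trials with exposure counts 1..5.
#'
#' @param schedule A [build_schedule()] result.
#' @return `TRUE` invisibly, or an error describing the violated invariant.
#' @export
validate_schedule <- function(schedule) {
  b1 <- schedule[schedule$phase == "baseline1", ]
  b2 <- schedule[schedule$phase == "baseline2", ]
  abort_if(nrow(b1) != 30L || any(b1$condition != "attend-Gabor"),
           "baseline1 must be 30 attend-Gabor trials")
  abort_if(nrow(b2) != 30L || any(b2$condition != "attend-Face"),
           "baseline2 must be 30 attend-Face trials")
  fb <- schedule[schedule$phase == "feedback", ]
  if (nrow(fb) == 0L) return(invisible(TRUE))
  abort_if(!identical(sort(unique(fb$epoch_number)), 1:3),
           "feedback phase must have epochs 1..3")
  for (ep in 1:3) {
    e <- fb[fb$epoch_number == ep, ]
    abort_if(nrow(e) != 50L, "feedback epoch ", ep, " must have 50 trials")
    runs <- rle(e$face_id)
    abort_if(length(runs$lengths) != 10L || any(runs$lengths != 5L),
             "feedback epoch ", ep,
             " must show 10 faces in runs of 5 consecutive trials")
    abort_if(anyDuplicated(runs$values) > 0L,
             "feedback epoch ", ep, " repeats a face across runs")
    abort_if(!all(e$exposure_count == rep(1:5, 10)),
             "exposure counts must be 1..5 within each face run")
  }
  invisible(TRUE)
}

#' Score every feedback trial of a recording
#'
#' Offline replay of the closed loop: each feedback trial's epoch is cut at
#' its marker and scored independently with [gabor_probability()], so scores
#' do not depend on processing order.
#'
#' @param rec An [eeg_recording()] whose markers cover all feedback trials.
#' @param model A calibrated `decoder_model`.
#' @param schedule The session schedule (or label table) identifying the
#'   feedback trials.
#' @param duration Epoch length in seconds.
#' @return Data frame with one row per feedback trial: `trial_index`,
#'   `face_id`, `epoch_number`, `exposure_count`, `probability`.
#' @export
run_offline_feedback <- function(rec, model, schedule, duration = 5) {
  abort_if(!inherits(model, "decoder_model"), "`model` must be a decoder_model")
  abort_if(is.null(model$platt), "model is not calibrated")
  fb <- schedule[schedule$phase == "feedback", , drop = FALSE]
  abort_if(nrow(fb) == 0L, "schedule has no feedback trials")
  missing <- setdiff(fb$trial_index, rec$markers$trial_index)
  abort_if(length(missing) > 0L,
           "no marker for feedback trial ", missing[1])
  epochs <- epoch_recording(rec, duration, labels = schedule)
  by_trial <- setNames(epochs,
                       vapply(epochs, function(e) e$trial_index, integer(1)))
  rows <- lapply(seq_len(nrow(fb)), function(i) {
    gabor_probability(model, by_trial[[as.character(fb$trial_index[i])]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize feedback scores in the per-participant report layout
#'
#' For each participant: the grand mean Gabor probability over the feedback
#' phase, the mean per face-exposure position 1-5, and the means over the
#' first and second halves of the feedback phase (trials 1-75 vs 76-150 at
#' the standard length, split by presentation order). Cells are rounded to
#' two decimals for reporting; the unrounded table is attached as attribute
#' `"raw"`.
#'
#' @param scores Data frame from [run_offline_feedback()] (columns
#'   `probability`, `exposure_count`, `trial_index`), optionally with a
#'   `participant` column for multi-participant tables.
#' @return Data frame with columns `participant`, `average`, `exposure_1` ..
#'   `exposure_5`, `first_half`, `second_half`.
#' @export
summarize_feedback <- function(scores) {
  abort_if(!is.data.frame(scores) || nrow(scores) == 0L,
           "`scores` must be a non-empty data frame")
  abort_if(!all(c("probability", "exposure_count") %in% names(scores)),
           "`scores` needs `probability` and `exposure_count` columns")
  if (is.null(scores$participant)) scores$participant <- 1L
  one <- function(df) {
    df <- df[order(df$trial_index %||% seq_len(nrow(df))), , drop = FALSE]
    n <- nrow(df)
    first <- seq_len(floor(n / 2))
    exp_means <- vapply(1:5, function(e) {
      mean(df$probability[df$exposure_count == e])
    }, numeric(1))
    c(average = mean(df$probability),
      setNames(exp_means, paste0("exposure_", 1:5)),
      first_half = mean(df$probability[first]),
      second_half = mean(df$probability[-first]))
  }
  parts <- split(scores, scores$participant)
  raw <- data.frame(participant = names(parts),
                    do.call(rbind, lapply(parts, one)),
                    check.names = FALSE, row.names = NULL)
  out <- raw
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], round, digits = 2)
  attr(out, "raw") <- raw
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
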