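---
title: "Decoding attentional competition from frequency-tagged EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding attentional competition from frequency-tagged EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssvepbci)
```

## The problem

When two visual stimuli flicker at different rates, each drives a steady-state
visual evoked potential (SSVEP) at its own flicker frequency and harmonics,
strongest over occipital cortex. Because the SSVEP amplitude at a tag
frequency grows with the attention allocated to the tagged stimulus,
superimposing a task-relevant stimulus (a Gabor patch, tagged at 12 Hz) on an
emotionally salient distractor (a sad or angry face, tagged at 8.57 Hz) lets a
classifier read out, trial by trial, which stimulus is winning the attentional
competition. That readout — expressed as a calibrated probability that
attention was on the Gabor — can be fed back to the participant as
neurofeedback for attention-bias modification training.

`ssvepbci` implements this pipeline offline: a synthetic frequency-tagged EEG
generator, FIR preprocessing and epoching, three spectral feature families, a
participant-specific SVM decoder with Platt-calibrated probabilities, the
session protocol, and the evaluation statistics (split-half reliability,
replication thresholds, paired effect sizes, repeated-measures ANOVA,
acceptability correlations).

## The session protocol

A session is two instructed baseline phases followed by a feedback phase:

* **Baseline 1** — 30 trials, attend the Gabor, ignore the face.
* **Baseline 2** — 30 trials, attend the face, ignore the Gabor.
* **Feedback** — 3 epochs of 50 trials. Within an epoch, 10 faces are drawn
  from the 30-face pool (15 actors, sad and angry versions) and each face is
  shown for 5 consecutive trials, so a participant can practice disengaging
  from that specific face; the per-trial Gabor probability is the feedback.

Every trial presents the superimposed pair for 5 s while EEG is recorded
continuously at 256 Hz. Face order is randomly permuted per phase under the
schedule seed. Which 10 of the 30 faces appear in a feedback epoch is not
fixed by the protocol description; we draw them without replacement per epoch
under the same seed, consistent with random permutation of display order.
"First half vs second half" of the feedback phase is read as trials 1–75
versus 76–150 in presentation order.

```{r schedule}
sched <- build_schedule(seed = 42)
table(sched$phase)
```

## The synthetic generator

No public recordings accompany this protocol, so the package ships a
first-class simulator whose defaults define the study conditions the test
suite exercises:

* Each tag contributes harmonics 1–3 of its fundamental with amplitude
  rolloff 0.5 per order, and a uniform random reference phase per trial (so
  phase-sensitive features are exercised honestly).
* The attended tag's harmonic stack is scaled by `attended = 1.0`, the
  unattended by `unattended = 0.3`. These weights are the package's
  "high-contrast" condition; real attentional modulation depths are not
  published for this protocol, so the defaults are chosen to represent a
  cooperative, high-SNR participant rather than any measured effect size.
* Background noise per channel is an equal-variance mix of 1/f pink noise
  (the standard EEG spectral background; exponent 1) and white Gaussian
  noise, with `snr = 1` meaning the attended fundamental's 1 µV amplitude
  equals the noise standard deviation.
* Topography: the tags appear at gain 1.0 on O1/O2/Oz — the SSVEP is
  generated in primary visual cortex — and at gain 0.3 on the 16 other
  recorded channels. The recorded montage lists 16 non-occipital sites while
  features are extracted from O1/O2/Oz; the package therefore models a
  19-channel montage carrying both sets.

What the simulator does **not** emulate: ocular and muscle artifacts, volume
conduction from a head model, non-stationary attention within a trial,
inter-trial amplitude drift, and realistic inter-participant variability.
Passing tests on simulated data therefore demonstrate the pipeline's
correctness and its behavior under controlled contrast and noise — not
expected decoding accuracy on recorded EEG.

```{r simulate}
cfg <- sim_config()
ep <- simulate_epoch(cfg, "attend-Gabor", seed = 1)
ep
```

## Preprocessing

All data are bandpass filtered to [1, 40] Hz with a linear-phase Kaiser FIR,
applied forward-backward so tag phase is undistorted. The protocol fixes only
the band, so the design parameters are package choices, logged in the filter
object: transition bands 0.75–2 Hz and 38–45 Hz, stopband deviation 0.001,
passband deviation 0.0575 (≤ 1 dB ripple). At 256 Hz this yields an
order-742 filter with single-pass attenuation of about 70 dB at 0.5 Hz and
78 dB at 45 Hz. Epochs start exactly at their trial marker (0-based sample
offsets), last `round(fs * duration)` samples, and receive no baseline
correction.

```{r filter}
spec <- design_bandpass(256)
spec
```

## Feature families

All features use the raw FFT of the 5-s epoch with FFT length equal to the
epoch length (1280 samples), i.e. 0.2 Hz bins and no zero padding:

* **PSD** — `(1/N)|X(f)|^2` of the time-domain average of O1/O2/Oz, one
  feature per bin in 1–40 Hz (196 features).
* **Power banks** — per channel, tag and harmonic `h = 1..n`, the power in
  `[h*f - f0, h*f + f0]` divided by the channel's total one-sided power
  (DC excluded); `f0` is the half-bandwidth (1.5 or 2 Hz in the standard
  menu). With 3 channels, 2 tags and 3 harmonics: 18 bounded features.
* **Cosine correlations** — Pearson correlation of each channel with
  `cos(2*pi*h*f*t)`, `t = (0..N-1)/fs`, phase 0.

Numerical choices worth stating: the 8.57 Hz tag is off the 0.2 Hz grid
(42.85 bins), so band membership is decided purely by bin-center inclusion in
the closed interval — deterministic and directly checkable against a
brute-force DFT. The power-bank denominator is the full one-sided spectrum
minus DC; since inputs are already 1–40 Hz filtered, the distinction from an
in-band sum is immaterial. The cosine-correlation family is normalized as a
Pearson correlation (the raw product it abstracts is unbounded and
scale-dependent; correlation makes the feature scale-free), and only
cosine-phase templates are used — no sine quadrature.

## The decoder

The participant-specific decoder is a two-class SVM (positive class:
attend-Gabor) over one of the feature families. Hyperparameters are not part
of the protocol description and are fixed package defaults, logged with every
model: `C = 1`, polynomial degree 3 with `coef0 = 1`, RBF and polynomial
`gamma = 1/(n_features * var(X))`. Features enter unscaled — power-bank and
correlation features are already bounded.

**Profiling.** `profile_configurations()` crosses the 14-configuration menu
(PSD ± forward selection; power banks over n = 1–3 and f0 ∈ {1.5, 2} with
selection at n = 3; cosine correlations n = 1–3 with selection at n = 3)
with the three kernels — 42 cells of seeded stratified 5-fold CV accuracy,
with per-cell wall-clock training time recorded (reported only, never
asserted). A selection rule returns the best cell, optionally excluding
forward-selection rows — the constraint applied when selection runtime would
delay a same-session protocol.

**Forward selection** grows a feature bank greedily from empty, scoring every
remaining candidate per step by CV misclassification on one fixed seeded fold
assignment, visiting candidates in seeded random order and breaking ties by
lowest feature index. It stops at the first non-improving step; the full
feature set is scored on the same folds as a fallback, so the returned subset
never does worse than using all features.

**Training** (`train_participant_decoder()`) is a seeded stratified 80/20
split of the 60 baseline trials: the SVM is fitted on the 48, the Platt
sigmoid `P = 1/(1 + exp(A*s + B))` is fitted on the 12 held-out decision
values (regularized targets, Newton iteration with backtracking), and the
recorded CV accuracy comes from the training portion. Balanced classes are
required; the stratified split then guarantees both classes in the
calibration set. Probabilities are monotone in the decision value by
construction.

```{r train}
sess <- simulate_session(cfg, build_schedule(seed = 7), seed = 7)
eps <- epoch_recording(sess$recording, 5, labels = sess$labels)
base <- eps[vapply(eps, function(e) e$phase != "feedback", logical(1))]
model <- train_participant_decoder(base, seed = 7)
model
```

## Evaluation layer

* **Replication threshold** — a ±10% relative band around a reference
  accuracy: `replication_interval(0.770)` gives (0.693, 0.847), and an
  observed accuracy replicates iff it falls inside.
* **Guttman split-half reliability** — trials are split odd/even by
  presentation order, aggregated per participant (mean; configurable to
  sums), and `lambda4 = 2*(1 - (V_odd + V_even)/V_total)` is taken across
  participants. The per-participant-mean aggregation is a package decision;
  the protocol description does not fix the aggregation unit.
* **Paired validation** — two-sided paired t-test between per-participant
  mean probabilities under the two baseline instructions, with the paired
  effect size `dz = t/sqrt(n)` (the between-condition pooled-SD variant is
  deliberately not used). Identical inputs are defined to give `t = 0`.
* **2×5 repeated-measures ANOVA** — Time (halves) × Trial (exposure 1–5)
  within-subject decomposition via `aov()` error strata, no sphericity
  correction, with `eta_p^2 = F*df1/(F*df1 + df2)` per effect. Degrees of
  freedom are computed from the design (Trial and interaction: F(4, 16) with
  5 participants), even where a report might print otherwise.
* **Acceptability correlations** — Pearson r and two-sided p per
  questionnaire item (seven items, 1–5 scale) against per-participant mean
  feedback probabilities; zero-variance items are reported as `NA` rather
  than erroring.

## Problem sizes used by the test suite

The suite validates properties at sizes a laptop handles comfortably, chosen
once as representative rather than tuned: the full 42-cell profiling grid
runs on one simulated high-contrast participant (60 baseline trials of 5 s);
chance level is estimated by 20 label permutations of that participant's
power-bank matrix; reliability uses a cohort of five pseudo-participants with
stable but heterogeneous attentional styles (three attending the Gabor
during feedback, two the face) completing the full 210-trial session;
contrast-recovery averages 20 seeds per contrast level using 30-trial,
1-s-epoch sessions at reduced SNR, where shorter epochs lower feature SNR
enough to see the accuracy gradient.

## Known limitations

* The simulator's effect sizes are not calibrated to any measured SSVEP
  amplitudes; published accuracies from recorded cohorts cannot be
  reproduced from simulation and are not targets of the test suite.
* Degenerate calibration splits (a validation fold collapsing to one class)
  are prevented by requiring balanced input rather than handled by refitting
  on training data.
* The cosine-correlation family is phase-sensitive by design; with the
  simulator's uniformly random trial phases its expected single-trial
  correlation is low, which is the realistic behavior for uncontrolled
  stimulus-EEG phase lags.
* No artifact rejection, re-referencing, or online (within-trial) decoding.
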