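Package: ssvepbci
Title: Frequency-Tagged SSVEP Attention Decoding and Neurofeedback Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Offline toolkit for steady-state visual evoked potential (SSVEP)
    neurofeedback experiments in which two superimposed stimuli flicker at
    distinct tag frequencies and the participant's attentional allocation is
    decoded from occipital EEG. Provides a synthetic frequency-tagged EEG
    simulator (harmonic tags in 1/f background noise), Kaiser FIR bandpass
    preprocessing and epoching, harmonic band-power / power spectral density /
    cosine-correlation feature extraction, participant-specific support vector
    machine decoding with forward feature selection and Platt probability
    calibration, session protocol scheduling with closed-loop feedback
    scoring, and the evaluation layer: Guttman split-half reliability,
    relative replication thresholds, paired effect sizes, two-way
    repeated-measures ANOVA, and acceptability correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
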