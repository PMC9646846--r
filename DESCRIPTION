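Package: eegconsensus
Title: Subjects'-Consensus Analysis of Action Concepts from EEG and Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for decoding action concepts from
    multi-subject EEG recordings and paired video descriptors. Provides a
    seeded multi-subject EEG simulator (shared concept vectors, subject-specific
    bias, band-limited oscillatory carriers), the standard hand-crafted EEG
    encodings (FFT band features, differential entropy, Morlet wavelet power,
    topographic EEG images), per-subject classifiers (MLP with dropout, linear
    SVM), subjects'-consensus prediction averaging with accuracy-versus-subjects
    curves and per-class ROC/AUC, generalized distillation of the EEG teacher
    consensus into a video-only student over a temperature/imitation-factor
    grid, and kernel/logit fusion baselines with a stratified stimulus-level
    split protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    kernlab,
    signal,
    jsonlite,
    tibble
Suggests:
    testthat (>= 3.0.0),
    pROC,
    ggplot2,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
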