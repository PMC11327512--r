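Package: vowelscreen
Title: Aspiration Screening from Paired Pre- and Post-Swallow Sustained-Vowel
    Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reusable pipeline for detecting dysphagia-aspiration from
    changes between pre- and post-swallow sustained-vowel ("ah") recordings.
    Standardizes heterogeneous clinical audio into fixed 2-second mono
    segments, pairs pre/post segments per subject, assigns subject-grouped
    stratified 10-fold cross-validation splits with minority-class
    oversampling, stores datasets hierarchically in HDF5, converts audio to
    128-band log-power Mel spectrograms, and trains a width-scalable
    dual-input inverted-residual convolutional change detector with dynamic
    waveform augmentation. Includes classification metrics with fold
    summaries, cohort contingency statistics, and a parametric source-filter
    vowel synthesizer with jitter, shimmer and harmonics-to-noise control for
    generating labeled test cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    rhdf5,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
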