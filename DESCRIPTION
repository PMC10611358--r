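Package: eegdep
Title: Frontal Six-Channel EEG Classification of Depressive Disorder
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for resting-state EEG classification of depressive
    disorder from six frontal channels. Provides a synthetic two-group EEG
    cohort generator (1/f background plus band-limited oscillations with
    controllable group band-power ratios and ocular artifacts), a
    preprocessing pipeline (downsampling, baseline correction, ICA artifact
    removal, 4-s epoching, 4th-order Butterworth band filtering), two
    multi-resolution 1-D convolutional classifiers (MRCNN with residual
    squeeze-and-excitation and self-attention; MRCNN with LSTM) implemented
    natively with analytic gradients, and a training/evaluation layer with
    warmup-cosine learning-rate schedule, stratified or subject-level k-fold
    cross-validation and confusion-matrix metrics. Reads and writes EDF.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
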