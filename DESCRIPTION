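Package: somnostage
Title: Automatic EEG Sleep Staging and Sleep-Architecture Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for single-channel EEG sleep staging and
    group-level sleep-architecture analysis. Provides a synthetic
    polysomnography generator with ground-truth hypnograms and
    stage-dependent spectral content, EEG preprocessing (resampling,
    zero-phase band-pass filtering, channel repair, ICA-based ocular
    artifact removal), extraction of twenty per-epoch time- and
    frequency-domain features including sample, fuzzy and multiscale
    entropy, decision-tree (Gini importance) feature selection, one-vs-rest
    support vector machine staging with subject-grouped cross-validation,
    hypnogram summary metrics (total sleep time, stage percentages, sleep
    efficiency, sleep onset latency, REM latency, awakening count), and
    two-group cohort statistics with bootstrap confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    rpart,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
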