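Package: eegemotion
Title: EEG Emotion Classification from Differential Entropy and Higuchi
    Fractal Dimension Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for binary emotion-state classification
    (valence/arousal and positive/negative) from multichannel EEG. Implements
    signal conditioning (integer down-sampling with anti-aliasing, zero-phase
    Butterworth band-pass, 50 Hz notch, pre-trial trimming, EEG-channel
    selection), non-overlapping temporal segmentation of trials, two
    time-domain feature extractors (histogram-estimated differential entropy
    and Higuchi's fractal dimension), four classifier families (k-nearest
    neighbours, support vector machine, extreme gradient boosting, classic
    gradient boosting) behind a single estimator contract, stratified k-fold
    and leave-one-subject-out cross-validation with full confusion/ROC
    reporting and paired t-test feature comparison, and a deterministic
    synthetic-data generator that emulates benchmark-shaped recording sets
    with class-conditional signal statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    class,
    e1071,
    grDevices,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils,
    xgboost,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
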