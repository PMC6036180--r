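Package: eegbrainage
Title: Brain Age Gap Estimation from EEG with Interpretable Features and
    Stacked Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end pipeline for predicting chronological age from
    resting-state EEG and deriving the brain age gap (BrainAGE, predicted
    minus chronological age). Reads EDF and BrainVision recordings, applies
    band-pass/notch filtering, resampling and bipolar montage derivation,
    segments recordings into overlapping epochs, and extracts an extensive
    interpretable feature set per channel and frequency band across five
    domains: amplitude statistics, range-EEG (peak-to-peak), Welch spectral
    measures, hemispheric connectivity (brain symmetry index, envelope
    cross-correlation, coherence) and Higuchi fractal dimension. Redundant
    features are removed by near-zero-variance and pairwise-correlation
    filters. Age is predicted with a nested cross-validated stack ensemble
    (elastic net, radial support-vector regression, random forest,
    gradient-boosted trees, polynomial-kernel Gaussian process regression,
    combined by a general linear model), with one-standard-error grid
    tuning, fold-robust feature importance, partial-dependence curves and
    channel-by-band importance maps. A synthetic EEG cohort generator with
    known age-dependent oscillatory structure supports validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    kernlab,
    ranger,
    Rcpp,
    signal,
    stats,
    tools,
    utils,
    xgboost
LinkingTo:
    Rcpp
Suggests:
    caret,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
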