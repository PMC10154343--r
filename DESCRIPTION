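Package: mifcat
Title: Auditory Categorization of Vocalizations by Most-Informative
    Spectrotemporal Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Hierarchical model of vocalization categorization: a
    cochleagram front-end turns calibrated audio into a dense
    time-frequency representation; sparse spectrotemporal feature
    detectors, learned by mutual-information threshold optimization and a
    greedy most-informative-feature search, vote with log-likelihood
    weights for call categories.  Includes calibrated degradations
    (additive white Gaussian noise at fixed SNR, reverberation with
    synthetic impulse responses quantified by T30), contrast gain
    control at the feature-matching stage, top-down modulation of
    detector thresholds driven by cochleagram statistics, ROC/d-prime
    evaluation, a go/no-go winner-take-all read-out with a logistic
    behavior-matching map, and a synthetic call generator so the whole
    pipeline runs end to end without recorded corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
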