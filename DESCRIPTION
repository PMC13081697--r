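Package: netdyn
Title: Time-Averaged and Transient Oscillatory Network Analysis for
    Parcellated Electrophysiological Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Characterises large-scale cortical networks in parcellated
    electrophysiological (MEG/EEG) recordings. Provides multitaper power
    and cross-spectral density estimation with DPSS tapers, coherence and
    canonical-band network summaries, time-delay embedding with group-level
    PCA, a zero-mean Gaussian-covariance Hidden Markov Model for transient
    network states (Baum-Welch EM with an optional stochastic mini-batch
    mode), state-dynamics summary statistics (fractional occupancy,
    lifetimes, intervals, switching rates), dual estimation of per-state
    spectra, and confound-aware sign-flip max-statistic permutation GLMs
    for group-level inference. Includes a synthetic cohort generator of
    Markov-switching oscillatory parcel time courses with configurable
    covariate effects for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
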