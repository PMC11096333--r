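Package: ospdecode
Title: Simulation, Measurement and Decoding of Auditory Omission ERPs
Version: 0.1.0
Authors@R: person("Omission ERP", "Maintainers", email = "ospdecode@example.org",
    role = c("aut", "cre"))
Description: Tools for studying omitted-stimulus potentials (OSPs) in
    multichannel EEG. Provides a trial-schedule builder for melody designs
    with probabilistic note omissions, a forward simulator that generates
    34-channel epochs with a frontocentral omission N1 component,
    note-identity-specific spatial patterns, colored spatially correlated
    background noise and threshold-detectable artifacts, an epoch
    preprocessing chain (zero-phase Hamming windowed-sinc band-pass,
    amplitude-based artifact rejection, baseline correction, participant
    inclusion gating), data-driven oN1 window measurement, time-resolved
    four-class One-vs-Rest linear SVM decoding with repeated k-fold
    cross-validation, and the accompanying statistics: paired and one-sample
    t tests with the dz effect size, default JZS Bayes factors, cluster-based
    sign-flip permutation tests over time, and noncentral-t power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
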