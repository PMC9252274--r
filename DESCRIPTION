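Package: fcsex
Title: Sex Differences in Resting-State Functional Brain Network Topology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis pipeline for sex differences in resting-state functional
    connectomes. Builds Fisher-z functional connectivity matrices from regional
    fMRI time series, computes weighted graph metrics (nodal strength, nodal
    efficiency, clustering coefficient) across a proportional-sparsity sweep
    with integration over sparsity levels, adjusts session-level metrics with
    linear mixed-effects models (random intercept per subject), tests sex
    contrasts with Bonferroni control, and performs network-based-statistic
    (NBS) permutation inference on inter-regional connectivity with
    subject-level label exchangeability. Includes a synthetic-cohort generator
    emulating a repeated-session aging cohort (covariates, amyloid PET SUVR
    classification, cognition scores linked to network topology) so the full
    pipeline is testable without access to restricted imaging data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    lme4,
    car,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
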