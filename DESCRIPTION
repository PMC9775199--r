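Package: uscphmd
Title: Umbrella-Sampling Constant-pH Molecular Dynamics on Model Systems
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A self-contained, desk-scale implementation of the stochastic
    titration constant-pH molecular dynamics (CpHMD) protocol coupled to
    umbrella sampling (US) along a one-dimensional reaction coordinate.
    Protonation and tautomer microstates are sampled by Metropolis Monte
    Carlo (single-site and pair moves), conformational degrees of freedom
    by overdamped Langevin dynamics on configurable model systems, and
    free-energy profiles are recovered by the weighted histogram analysis
    method (WHAM) with bias re-weighting of protonation observables,
    Hill-curve pKa fitting, pKmod calibration, and split-half and
    autocorrelation-block error estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
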