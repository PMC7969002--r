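Package: clampdyn
Title: Conformational Dynamics of the RNA Polymerase Clamp from smFRET Time Traces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of single-molecule FRET time traces of the bacterial RNA
    polymerase clamp: apparent FRET efficiency and stoichiometry calculus with
    ALEX-based trace selection, variational-Bayes hidden Markov model inference
    with lower-bound model selection, kinetic post-processing (transition rates
    with group errors, dwell times, occupancies, static/dynamic classification,
    missed-dwell and long-dwell statistics), per-state histogram Gaussian fits,
    and a Monte-Carlo simulator of multi-state FRET trajectories including
    frame-binning emulation of slow acquisition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
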