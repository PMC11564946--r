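Package: cicadaclock
Title: Rate-Time Analysis, Fossil Calibration Priors, and Relaxed-Clock
    Simulation for Dated Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing time-dependent substitution rates on
    Bayesian relaxed-clock timetrees. Builds minimum-age (tMRCA) normal
    calibration priors from geological stage bounds, radio-isotopic dates,
    or dated geological events; reads and writes rooted ultrametric trees
    annotated with per-node posterior age, rate median, and posterior
    probability (the FigTree/NEXUS metadata-comment dialect); extracts
    rate-versus-age node tables and fits the exponential rate-time model
    r(t) = r0 * exp(b * t) by log-linear least squares; and diagnoses
    substitution saturation from transition/transversion counts against
    Kimura two-parameter corrected distances. A built-in simulator of
    Yule timetrees with uncorrelated-lognormal branch rates (optionally
    exponentially time-dependent) and HKY+Gamma sequences provides ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    yaml,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    Matrix,
    optparse
Config/testthat/edition: 3
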