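Package: midest
Title: Maximally Informative Dimensions for Multicomponent Receptive Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of multicomponent linear-nonlinear (LN) receptive
    field models by maximally informative dimensions (MID): gradient ascent
    with simulated annealing on the mutual information between stimulus
    projections and spikes, in both joint and sequential (orthogonal
    complement) modes, under a four-fold jackknife protocol.  Includes LN
    model-cell simulators with Gabor spatiotemporal filters (OR-threshold,
    divisive gain control, and quadratic gain families), synthetic white-noise
    and naturalistic stimulus ensembles, a minimal projection pursuit
    regression baseline, and evaluation tools: subspace projection overlap,
    percent information explained, signal-to-noise maps, and spike-budget
    convergence experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
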