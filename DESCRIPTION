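Package: riceSiDyn
Title: Whole-Plant Silicon Dynamics in Rice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates silicon (Si) dynamics in a whole rice plant on a network of
    hydraulic nodes. Couples an electric-circuit analogy for xylem and phloem water
    flow with diurnal sucrose/starch carbon dynamics, a two-compartment root Si
    uptake model with a transporter expression factor, advective Si transport and
    enriched partitioning between vascular bundles at stem nodes, and a shoot-to-root
    signaling substance that regulates root transporter expression under
    accumulation-, shortage-, or water-stress-control hypotheses. Includes an
    investment-efficiency analysis of transporter expression, a carbon-parameter
    stability scan, boundary-condition generators (artificial diurnal cycles and
    eddy-covariance field data), and Metropolis-Hastings calibration of root
    transporter parameters against xylem-sap Si time series.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
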