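Package: freerunfw
Title: Free-Running Chemical-Shift-Encoded Cardiac MRI Simulation and
    Fat-Water Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for free-running
    chemical-shift-encoded (CSE) cardiac MRI at 3T. Implements a
    multi-peak fat-water signal model with joint B0 and R2* estimation
    (IDEAL-type variable projection with a spatially constrained field
    map), in-silico accuracy studies of proton-density fat fraction
    (PDFF) quantification under monopolar and bipolar multi-echo readout
    schemes, gradient impulse response function (GIRF) characterization
    and k-space trajectory correction, 3D radial spiral-phyllotaxis
    trajectory generation, and a desk-scale motion-resolved
    compressed-sensing reconstruction with cardiac and respiratory
    self-gating.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    RNifti,
    Rcpp,
    signal,
    splines,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
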