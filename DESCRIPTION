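Package: landrec
Title: Landscape Complexity and Population Recovery After Disturbance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and estimation toolkit for studying how landscape
    complexity shapes the long-term dynamics of animal populations.
    Generates synthetic raster patch mosaics emulating an agricultural
    landscape, applies three complexity-reduction transforms (patch-shape
    homogenization, within-size-class arrangement randomization, and
    unconstrained size randomization), runs desk-scale spatially explicit
    individual-based models for four life-history archetypes (ground
    beetle, field vole, skylark, linyphiid spider) under a periodic
    population-removal protocol, and estimates equilibrium population size
    (K) and return time (phi) by fitting logistic recovery curves on log
    abundance with weather-year random asymptotes and parametric-bootstrap
    confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    nlme,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
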