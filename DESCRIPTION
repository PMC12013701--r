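Package: tallgrass
Title: Grid-Based Tallgrass Prairie Ecohydrology, Fire and Fuel-Load Simulation
Version: 0.1.0
Authors@R:
    person("Konza", "Modeling Group", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale, spatially distributed ecohydrological model of
    tallgrass prairie in the Flint Hills style: daily four-layer soil water
    balance on a flow-routed elevation grid, coupled carbon and nitrogen
    cycling with water/nitrogen/temperature co-limitation of plant nitrogen
    uptake, prescribed fire with nitrogen volatilization and ash return, a
    grazer nitrogen budget, and surface fuel-load accounting. Includes
    stochastic generators for the daily weather, ridge-valley terrain,
    topographic soil profiles, treatment parcels and burn-scar rasters that
    such simulations require, mass-conserving ledgers for water, carbon and
    nitrogen, and experiment harnesses for grid-resolution and grazed versus
    ungrazed twin comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
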