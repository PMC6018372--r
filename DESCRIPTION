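Package: lcstrain
Title: Digital Volume Correlation and Strain Mapping for Lamina Cribrosa
    Inflation Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing ex vivo inflation experiments on the optic
    nerve head imaged by volumetric (second-harmonic-generation) microscopy.
    Recovers three-dimensional displacement fields between pressurised image
    volumes by fast-Fourier-transform based iterative digital volume
    correlation (DVC), smooths them with sixth-order trivariate polynomials,
    derives Green-Lagrange, principal and maximum-shear strain fields,
    partitions the lamina cribrosa into anatomical analysis regions about the
    central retinal vessels, quantifies thickness changes and DVC measurement
    error, and runs paired nonparametric and generalized-estimating-equation
    statistics on regional strain summaries. Includes a synthetic phantom
    generator with analytic ground-truth deformations for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    tools,
    utils,
    Rcpp,
    tiff,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
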