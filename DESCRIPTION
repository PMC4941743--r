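Package: enamelD
Title: Fractal Dimension of Occlusal Enamel Bands and Phylogenetic
    Comparative Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the fractal dimension (D) of binary traces of
    occlusal enamel bands by the box-counting method, summarises
    specimen-level measurements to species means, and relates enamel
    complexity to occlusal surface area across equid tribes with Welch
    t-tests and generalized least squares regression under Pagel's
    lambda residual covariance (PGLS), including maximum-likelihood
    lambda estimation with profile-likelihood confidence intervals.
    Includes fossil-range (FAD/LAD) time calibration of supertrees with
    a zero-length-branch adjustment, synthetic generators for curves of
    known fractal dimension, pure-birth trees and lambda-structured
    trait data, and an end-to-end pipeline from images to report
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    nlme,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
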