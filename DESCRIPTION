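Package: hyenamorph
Title: Landmark Morphometrics and Spatial Macroecology of Skull Size
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for landmark-based analysis of geographic
    variation in skull size. Implements generalized Procrustes
    superimposition with bending-energy sliding of semilandmarks and
    centroid-size extraction from tpsDig-style landmark files; universal
    kriging of population-density point estimates under a stable
    semivariogram model; Jenks natural-breaks classification; trend-surface
    polynomial regression of centroid size on geography with AIC subset
    selection, variance-inflation diagnostics and backward stepwise
    reduction; and sexual-size-dimorphism ratio summaries by geographic
    region. A seed-explicit synthetic-data generator emulates museum
    specimen collections, census-derived density tables and gridded
    climate covariates so that the whole chain is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    geosphere
Suggests:
    testthat (>= 3.0.0),
    withr,
    car,
    lmtest,
    vegan,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
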