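Package: soilgrade
Title: Soil Fertility Grading by Attribute Recognition with Entropy Weights
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Multi-indicator soil fertility assessment for land-use and
    restoration chronosequence studies. Computes piecewise-linear
    single-index attribute measures of nutrient values against a grade
    standard matrix, Shannon entropy weights for the nutrient indexes
    within each land-use or restoration-age group, comprehensive
    attribute measures with confidence-criterion grade classification
    and score ranking, and the accompanying group statistics (means,
    coefficients of variation, one-way ANOVA with pairwise-LSD compact
    letter displays, and a weight-spread convergence metric). Includes a
    seeded synthetic-data generator emulating a five-land-use design
    with a 0-25 year restoration chronosequence and five replicates per
    group.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
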