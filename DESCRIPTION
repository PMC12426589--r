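Package: bruvkit
Title: Spatially Balanced Stereo-BRUV Survey Design and Analysis
Version: 0.1.0
Authors@R: person("bruvkit", "maintainers", email = "bruvkit@example.org",
    role = c("aut", "cre"))
Description: End-to-end toolkit for baited remote underwater video (BRUV)
    surveys: spatially balanced stratified site selection (GRTS with a
    minimum-spacing rule), ingestion of frame-level annotation tables,
    MaxN relative abundance, Shannon diversity, length-weight biomass with
    a proxy-length cascade, bathymetric terrain covariates, collinearity
    screening, spatially lagged GLM candidate sets ranked by AICc,
    incidence-based rarefaction/extrapolation with a Chao2 asymptote, and
    a seeded synthetic-seascape generator with recorded ground truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
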