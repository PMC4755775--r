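Package: suscept
Title: Invasion Susceptibility Mapping by Prediction-Convergence Ensemble Habitat Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Habitat-suitability modelling framework for mapping susceptibility to
    biological invasion. Builds spatially constrained pseudo-absence datasets
    (distance-filtered records of non-target congeners plus buffered random
    points), fits a battery of presence/pseudo-absence learners over a
    runs-by-pseudo-absence design, selects models in three stages (True Skill
    Statistic cut, invasive hit-rate cut, prediction-convergence sweep over mean
    pairwise Pearson correlation), and composes committee-style ensembles:
    agreement-level maps, overall-prediction maps, and a classed susceptibility
    map. Includes a virtual-species synthetic-landscape generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    mgcv,
    glmnet,
    xgboost,
    ranger,
    geosphere,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
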