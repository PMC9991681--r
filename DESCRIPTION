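Package: foodaccess
Title: Food-Environment Accessibility and Spatial Food-Insecurity Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the relationship between patient-reported food
    insecurity and geographic access to healthful grocery stores. Implements
    NEMS-S (Nutrition Environment Measures Survey in Stores) sub-score and
    total-score arithmetic, patient-store distance matrices with radius
    exposure summaries (maximum, mean, presence) and an accessibility
    area-under-the-curve statistic, chained-equation multiple imputation with
    a random-forest base learner and Rubin's-rules pooling, pooled linear and
    logistic exposure models with effect modification by area vehicle
    availability, and spatial relative-risk surfaces from symmetric adaptive
    kernel density ratios with permutation tolerance contours. A seeded
    synthetic-city generator provides cohorts with the statistical structure
    the analysis assumes, so the whole pipeline runs with no external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    randomForest,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS
Config/testthat/edition: 3
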