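Package: reefsdm
Title: Shelf-Edge Grouper Distribution Models and Marine Reserve Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling the distribution of rare shelf-edge reef
    fishes from sparse, multi-gear presence-absence records, and for scoring
    marine protected areas against the resulting maps. Implements a rule-based
    habitat suitability classification on a one-arcminute depth-grid
    (Known / Probable / Not suitable / Unknown), a logit-link binomial
    occurrence model with gear standardization and a 32-candidate term
    structure set, model selection by AIC and by repeated k-fold
    cross-validation with ROC-derived classification thresholds, and
    reserve protection accounting (percent of habitat class, area-weighted
    percent of stock, protection per unit area, partial-efficiency
    weighting). A seeded synthetic-data generator emulates the statistical
    structure of shelf-edge survey data (2-7 percent occurrence, clustered
    hardbottom, gear-biased sampling effort) and exports ground truth for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
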