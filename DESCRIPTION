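Package: ivepart
Title: Exact Hierarchical Partitioning and Variable-Ranking Stability Audits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Exact, order-invariant hierarchical partitioning of regression
    goodness-of-fit (the Shapley/LMG decomposition) into independent and joint
    contributions per predictor, for Gaussian, binomial and Poisson models.
    Includes a permutation audit that quantifies the stability of
    variable-importance rankings under reordered predictors, multivariate
    normal and presence/pseudo-absence data generators for simulation studies,
    and an AICc-based mixed-model workflow (candidate-set enumeration with a
    collinearity screen, Akaike weights, confidence sets and model averaging)
    for modelling the probability that a variable changes rank as a function
    of spacing in independent explained variance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
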