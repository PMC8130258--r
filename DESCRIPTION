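Package: fsbn
Title: Bayesian Belief Networks for Household Food Security Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete Bayesian belief network modelling of household food
    security from census-style household surveys. Learns network structure
    from ordinal household data with the Max-Min Parents and Children (MMPC)
    algorithm using a stratified Jonckheere-Terpstra conditional-independence
    test, constrains edge directions by a level-wise causal ordering
    (optionally seeded with an expert-elicited network as a prior), estimates
    conditional probability tables by maximum a posteriori with add-one
    smoothing, answers exact observational and interventional (do-operator)
    queries, validates predictions by k-fold cross-validation under the Brier
    score, information reward and Bayesian information reward, and ranks
    drivers of food security by mutual-information and change-of-belief
    sensitivity. Includes a synthetic household-data generator so the whole
    pipeline is testable without access to restricted surveillance data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
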