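Package: umbrellar
Title: Umbrella-Species Surrogacy Evaluation with Greedy Spatial Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates how well focal conservation areas delineated for a single
    umbrella species cover the distributions of co-occurring species, by comparing
    per-species coverage against a random-placement baseline and against equal-area
    multi-species prioritizations produced by a Zonation-style greedy cell-removal
    ranking (additive-benefit and core-area marginal-loss rules, hierarchical
    removal masks). Also quantifies threat exposure (land-use change scenarios,
    invasion risk) inside focal areas versus the whole study region, and ships a
    synthetic-landscape generator (autocorrelated species distributions with a
    controllable range-size spectrum and controllable association with the
    umbrella species) so the full analysis is exercisable without external GIS
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
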