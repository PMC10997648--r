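Package: defoeval
Title: Quasi-Experimental Evaluation of Forest Conservation on Simulated Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating the relative performance of community forest
    management and state protected areas in reducing deforestation, using
    statistical matching and event-study panel regression. Constructs annual
    deforestation outcomes from gridded forest cover at multiple resolutions,
    draws spatially balanced samples of forested grid cells, performs 1:1
    genetic matching with replacement (exact within vegetation zones) with
    covariate-balance diagnostics, and estimates yearly crisis and post-crisis
    effects with grid-cell fixed effects and cluster-robust (one-way and
    multiway) standard errors. Includes a synthetic-landscape simulator with
    spatially autocorrelated confounders, accessibility-driven treatment
    assignment, and an absorbing forest-loss hazard with configurable yearly
    treatment effects, so every stage of the pipeline can be exercised against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    EBImage,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    sandwich,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
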