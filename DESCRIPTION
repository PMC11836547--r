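Package: paleoshift
Title: Hindcasting Species Range Shifts with Dispersal-Limited Distribution Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A testbed for evaluating how the predictive performance of
    species distribution models degrades in climates increasingly dissimilar
    from their calibration period. Generates a synthetic Holocene-like world
    (gridded climate trajectory with abrupt early warming, a mechanistic
    species fitness truth, and virtual fossil-pollen archives), fits three
    surrogate model families (a correlative classifier, an expert process
    model, and an inverse-calibrated process model), propagates their
    suitability maps through a dispersal-limited cellular automaton with
    fat-tailed kernels, converts pollen archives to gridded presence/absence,
    quantifies climatic dissimilarity via bootstrapped kernel-density
    hypervolume overlap, and relates hindcast skill (Sørensen index) to
    dissimilarity with a Bayesian ordered beta regression that accounts for
    predictor measurement error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
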