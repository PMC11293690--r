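Package: platekin
Title: Spatially Coupled Growth Kinetics of Microbial Colony Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing dense arrays of microbial colonies growing on a
    shared solid-medium plate. Implements a nested hierarchy of growth-rate
    models for 32 x 48 colony grids: a plate-mean null model, Baranyi-Roberts
    lag-phase adjustment with a two-stage local/global fitting protocol,
    layer-resolved mechanism-free corrections, a density-dependent
    consumer-resource model with a latent nutrient integral, and a low-parametric
    consumer-resource model in which an unobserved resource field diffuses across
    a padded lattice (mean-field Moore-neighbourhood diffusion, explicit Euler
    integration, doubly-iterative inference). Includes random-forest
    feature-importance analyses of growth determinants over time, model
    comparison by sum-of-squared-error decompositions and AIC, and a forward
    simulator used as a synthetic-data generator for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    minpack.lm,
    randomForest,
    stats,
    utils
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
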