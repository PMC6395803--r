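Package: eivsdm
Title: Site Ecological Indicator Values as Predictors in Species
    Distribution Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to test whether community-mean ecological indicator
    values (site EIVs, e.g. Landolt or Ellenberg scores averaged over the
    species recorded at a vegetation plot) carry environmental signal that
    mapped predictor layers miss.  The package simulates mountainous
    landscapes with latent environmental gradients and imperfect mapped
    proxies, assembles virtual plant communities from Gaussian niches,
    computes leave-one-out site EIVs, fits species distribution models
    (GLM, GAM, random forest, a maximum-entropy-style regularized model,
    and surface range envelopes) under systematically substituted
    predictor sets, and quantifies performance changes (AUC, TSS, kappa,
    accuracy, explained deviance), permutation variable importance, and
    the spatial mappability of each indicator dimension under repeated
    70/30 cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    mgcv,
    purrr,
    ranger,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
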