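Package: rvcascade
Title: Eliminative Radial-Visualization Cascades for Therapy-Response
    Prediction from Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and applying step-by-step eliminative
    classifiers on radial (RadViz) linear projections of gene expression.
    Includes moderated t-statistic differential expression with empirical
    Bayes variance shrinkage, a two-stage cross-cohort marker-selection
    procedure, spring-equilibrium projection onto circular anchor layouts,
    sector-region elimination cascades (training and application), a
    published four-step FOLFOX-response cascade preset, GEO Series Matrix
    input/output, and a synthetic cohort generator with block-correlated
    marker panels and resistant-subtype heterogeneity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
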