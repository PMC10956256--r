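Package: elpgv
Title: Ensemble Learning for Prediction of Genetic Values
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ensemble genomic prediction that combines genetic-value predictions
    from several whole-genome regression methods (GBLUP and the Bayesian alphabet:
    BayesA, BayesB, BayesCpi) through a weighted average whose weights are trained
    by a hybrid differential-evolution / particle-swarm optimizer maximizing the
    Pearson correlation between the ensemble prediction and a target (observed
    phenotypes, or reference genetic values from the best-fitting base method when
    test phenotypes are unknown). Ships reference implementations of the base
    learners, a quantitative-trait simulator with gamma-distributed QTL effects,
    and a Monte-Carlo cross-validation benchmark with paired-sample t-tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
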