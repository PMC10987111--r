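Package: bkscore
Title: Graph-Attention Scoring of ADC Payload Bystander-Killing Potential
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Ranks candidate antibody-drug-conjugate (ADC) payloads for
    bystander-killing potential from their SMILES structures. Implements a
    multi-head graph-attention network (GAT) regressor over molecular graphs
    with an invertible label normalizer, seeded 8:1:1 random splitting,
    Pearson R-squared evaluation and bounded random hyperparameter search;
    Morgan-fingerprint baseline regressors (support vector regression,
    gradient-boosted trees, Bayesian ridge, random forest) for protocol
    comparison; and a calibrated scoring layer that combines a permeability
    model (B score, log10 apparent permeability in nm/s, bystander cut at
    1.5) with a potency model (K score, pIC50-style) into a reference-
    calibrated B-K score for candidate triage. A synthetic-molecule generator
    with a graph-computable ground-truth label function makes the whole
    pipeline testable without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    dplyr,
    e1071,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
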