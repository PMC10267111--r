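Package: bridgenet
Title: Symptom-Biomarker Network Analysis with Bootstrap Stability and
    Network Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Estimates regularized partial-correlation networks (Gaussian
    graphical models) over mixed ordinal, binary and continuous clinical
    variables, as used to study comorbid depressive symptoms, suicidality
    and stress-axis biomarkers. Provides two-step polychoric, tetrachoric
    and polyserial correlations, an EBIC-selected graphical lasso,
    expected-influence and bridge centrality, focal-node predictive
    betweenness and flow views, nonparametric and case-dropping bootstrap
    stability (CS-coefficient), a permutation network comparison test, and
    a latent-Gaussian synthetic cohort generator with known ground truth
    for validation.
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
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    mvtnorm,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
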