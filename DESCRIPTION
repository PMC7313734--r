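Package: fluenet
Title: Semantic Networks from Repeated Verbal Fluency, with Default Bayesian Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates an individual semantic network from repeated semantic
    fluency lists (e.g., animal naming) under a censored random walk retrieval
    model with a Bernoulli edge prior anchored to a reference association
    network, maximized by seeded stochastic search. Computes the graph
    statistics used in the individual-differences literature (average shortest
    path length, clustering, optimal modularity, small-world index), default
    Bayes factors (JZS independent-samples t-test; Pearson correlation under a
    uniform or directional prior on the population correlation) from summary
    statistics, majority-consensus creativity scoring with Cohen's kappa, a
    synthetic cohort generator with configurable effect structure, and a
    pipeline that chains cleaning, estimation, metrics and the Bayesian test
    battery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
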