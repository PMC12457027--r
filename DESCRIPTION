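Package: rolelearn
Title: Trial-by-Trial Models of Social Role Learning with
    Similarity-Based Generalization
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Simulates and fits trial-by-trial computational models of how
    people learn the trait profile of a social role from feedback.  Five
    candidate models span a no-learning regression on self-ratings, fine
    granularity learning that spreads prediction errors across traits
    through an inter-trait similarity matrix, asymmetric (dissonance
    dependent) learning rates, and self-concept anchoring via a mixing
    weight gamma.  Subjects are fitted by MAP estimation with Laplace
    model evidence under wide Gaussian priors; cohorts are compared with a
    random-effects hierarchical scheme yielding model frequencies,
    exceedance probabilities and protected exceedance probabilities.
    Includes a synthetic-task generator (rater pools, similarity
    matrices, agents for every model) and the standard validation suite:
    parameter recovery, model confusion, optimality (feedback-optimal
    parameter) control, and posterior-predictive checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
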