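Package: twostepr
Title: Hybrid Model-Based/Model-Free Reinforcement Learning for the Two-Stage Markov Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for the two-stage Markov decision
    task used to dissociate goal-directed (model-based) from habitual
    (model-free) choice. Provides the task environment (70/30 transition
    structure, Gaussian random-walk reward probabilities with reflecting
    boundaries), a seven-parameter hybrid reinforcement-learning agent
    combining SARSA(lambda) model-free values with Bellman model-based values
    under a softmax choice rule with perseveration, maximum-likelihood
    parameter estimation via grid search plus multistart bounded refinement,
    stay-probability and strategy-score analysis, and synthetic-cohort
    generation with end-to-end parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    purrr,
    tidyr,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
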