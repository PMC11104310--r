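Package: gonogo
Title: Reinforcement-Learning Analysis of Orthogonalized Go/No-Go Tasks and
    Activity Diaries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying Pavlovian and instrumental learning in
    depression treatment research. Implements the orthogonalized Go/No-Go
    task (a 2x2 design crossing required action with outcome valence under
    80/20 probabilistic feedback), a nested family of Rescorla-Wagner
    learning models with go bias, irreducible noise and separate appetitive
    and aversive Pavlovian weights that may change across repeated task
    administrations, hierarchical empirical-Bayes fitting by
    expectation-maximization with Laplace approximations and integrated-BIC
    model comparison, posterior-predictive learning curves, classical
    behavioural summaries (condition accuracies, Pavlovian bias indices,
    congruency tests, repeated-measures ANOVA), mixed-effects regressions
    linking weekly symptom trajectories to fitted parameter changes,
    reinforcement-learning analyses of daily activity diaries
    (prediction-error updating, choice repetition, anhedonia-item
    interactions), and synthetic-data generators with known ground truth for
    every input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
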