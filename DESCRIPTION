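Package: mealrl
Title: Personalized Meal Planning with Collaborative Filtering and
    Reinforcement Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Interactive meal-plan recommendation combining latent-factor
    collaborative filtering with a deep Q-network agent. User taste is
    encoded as a latent vector learned by bias-augmented stochastic
    gradient matrix factorization of a sparse user-meal rating matrix;
    the latent vector serves as the reinforcement-learning state and is
    updated online as ratings arrive. Rewards blend three components:
    the user's normalized rating, a fuzzy nutrition-adequacy score
    (the Prerow value, built from per-nutrient trapezoidal membership
    functions), and a multi-criteria preference score obtained from AHP
    criterion weighting followed by TOPSIS ranking. Includes a seeded
    synthetic world generator (meal catalogues with realistic nutrient
    vectors, users with low-rank taste structure, simulated ratings), a
    simulated-user environment, baseline recommenders, and an evaluation
    harness that compares methods on average nutrition, preference, and
    acceptance scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    Matrix,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
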