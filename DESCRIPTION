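Package: igtrl
Title: Reinforcement-Learning Models and Choice Patterns for the Iowa
    Gambling Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for the Iowa gambling task:
    the standard four-deck payoff environment, the Outcome-Representation
    Learning (ORL) and Value plus Sequential Exploration (VSE)
    reinforcement-learning models together with the classical EV, PVL,
    EV-PU and PVL-Delta models as simulators and likelihoods, broad and
    restricted choice-pattern classification with sequential-exploration
    indices, parameter space partitioning over full parameter grids,
    generation of simulated cohorts with controlled pattern composition,
    and hierarchical Bayesian estimation with AIC, BIC and WAIC model
    comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
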