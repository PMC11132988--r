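Package: phenodyn
Title: Dynamic Computational Phenotyping of Cognitive Task Batteries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating and analysing dynamic computational
    phenotypes from longitudinal cognitive task batteries. Provides
    trial-level likelihood models and matched simulators for seven tasks
    (Pavlovian Go/No-go, colour change detection, random dot motion via the
    drift diffusion model, risky lottery choice, hyperbolic intertemporal
    choice, a Kalman-filter two-armed bandit with a probit exploration
    policy, and Weber-fraction numerosity comparison); three hierarchical
    Bayesian statistical models over week-level phenotypes (independent,
    reduced, and a dynamic model with power-law practice and affective
    state terms) fitted with an adaptive Hamiltonian Monte Carlo sampler;
    survey-based valence/arousal state extraction via PCA; psychometric
    analytics including bootstrapped ICC(2,1), relative contributions,
    probability of direction, and power-law practice-curve fits with
    permutation tests; and a synthetic-cohort generator with retained
    ground truth for parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
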