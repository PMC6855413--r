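Package: twosteptask
Title: Simulation, Hierarchical Model Fitting and Reliability Analysis for
    the Two-Step Decision Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the sequential two-step decision task used to
    dissociate model-free (habitual) from model-based (goal-directed)
    control. Provides a generative task model with Gaussian random-walk
    reward probabilities, a family of hybrid SARSA(lambda)/model-based
    reinforcement-learning agents, hierarchical empirical-Bayes (EM)
    fitting with integrated-BIC model comparison, stay/switch
    mixed-effects regression, a simulation mapping model parameters onto
    regression coefficients, test-retest reliability (ICC, CV) and power
    machinery, and a minimal near-infrared-spectroscopy processing chain
    (modified Beer-Lambert conversion and trial-wise GLM amplitudes).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    lme4,
    lmerTest,
    car,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
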