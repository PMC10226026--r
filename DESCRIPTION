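Package: pemem
Title: Prediction Error and Episodic Memory: Contingency-Task Simulation,
    Reinforcement-Learning Model Fitting, and Subsequent-Memory Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for model-based analysis of how prediction error at
    encoding relates to episodic recognition memory.  Simulates probabilistic
    context/object-category contingency learning tasks, fits four delta-rule
    reinforcement-learning models (decreasing, decreasing-free, free
    instructive, and free evaluative learning rates) to choice data by
    maximum likelihood, compares them by BIC with evidence grading, derives
    trial-level unsigned and signed prediction errors, scores recognition
    memory with permutation-based at-chance exclusion, and fits mixed-effects
    logistic subsequent-memory models with prediction-outcome interactions,
    simple slopes, and binned-PE follow-ups.  Includes parameter- and
    model-recovery diagnostics and a fully seeded synthetic-study generator
    so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    emmeans,
    jsonlite,
    lme4,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
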