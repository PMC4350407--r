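Package: rewardbias
Title: Reward-Induced Bias Acquisition in Perceptual Decisions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and model-based analysis of a two-context random-dot
    motion discrimination task with asymmetric reward payoffs. Generates
    counterbalanced trial schedules with truncated-exponential inter-trial
    intervals, simulates Q-learning agents whose choices follow a logistic
    psychometric rule biased by learned action values, fits context-dependent
    and context-free reinforcement-learning choice models by maximum
    likelihood, compares them by group AIC and by hierarchical (random
    intercept) logistic regression likelihood-ratio tests, derives per-trial
    indecision points and bias amounts, runs residual autocorrelation
    diagnostics, and exports model-derived parametric modulators as FSL
    three-column event files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    lme4,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
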