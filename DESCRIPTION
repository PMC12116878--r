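Package: prefrl
Title: Preference-Seeded Reinforcement Learning for Two-Stage Choice
    Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation and analysis of two-stage behavioural experiments
    in which preferences formed by free choice (internally guided
    decision-making) may seed the initial values of subsequent reward
    learning in a gambling task (externally guided decision-making).
    Provides four Q-learning variants that differ only in how initial
    values are assigned to high-preference, low-preference and novel
    stimuli; exact session likelihoods with a compiled core; tempered
    posterior Markov chain Monte Carlo fitting with WBIC model comparison
    and Kass-Raftery Bayes factor categories; learned-value trajectory
    extraction; the behavioural test battery (paired contrasts,
    repeated-measures ANOVA with partial eta squared, Holm-corrected
    rating comparisons, first-trial choice proportions); and parameter
    and model recovery studies on fully synthetic data matching the
    two-armed bandit design (seven-stimulus preference phase, three fixed
    pairs at 70%/30% Bernoulli reward).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
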