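Package: sociogaze
Title: Gaze-Contingent Social Interaction Simulation and Bayesian Observer Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying active information gathering in nonverbal
    human-robot-robot interaction. Builds a gesture-perception model from
    Likert ratings of robot gestures (valence and normalized-entropy ambiguity
    scores, Bayes-inverted relationship-to-gesture likelihoods), generates
    constrained relationship matrices by exhaustive multiset-permutation
    search, simulates gaze-contingent interaction sessions with pluggable gaze
    policies and synthetic trait-linked cohorts, runs a Bayesian ideal
    observer over observed gestures, and scores sessions with the
    behavioral-error (distance from a greedy information-optimal agent) and
    learning measures, plus cohort-level round-dynamics tests, trait
    correlations and a parameter-recovery harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
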