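Package: emibandit
Title: Thompson-Sampling Behavior Recommendation and Longitudinal Analysis
    for Mobile Obesity Interventions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating an ecological momentary
    intervention (EMI) that recommends daily weight-loss behaviors with a
    per-user beta-Bernoulli multi-armed bandit driven by Thompson sampling.
    Provides the bandit engine (beta posterior over per-behavior completion
    probability, seeded reproducible ranking, review-driven updates), a
    JSON-lines event-log data model for set/review cycles with daily mood
    (9-item visual-analog scale scored into depression, anxiety, and
    positive-affect subscales) and daily weight, set-review pairing under a
    12-36 hour window, feasibility metrics (app use rates), a synthetic
    cohort simulator with AR(1) mood dynamics and mood-modulated behavior
    completion, and the study-style statistical pipeline: exact and
    approximate Wilcoxon signed-rank tests, two-level linear mixed-effects
    models fit by maximum likelihood with AIC-based model selection, and a
    simulation harness for parameter-recovery and confidence-interval
    coverage diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
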