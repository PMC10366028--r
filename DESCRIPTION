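Package: epelir
Title: Scoring, Simulation and Psychometrics for the EPELI Virtual-Apartment Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless toolkit for the EPELI ("Executive Performance in
    Everyday LIving") naturalistic assessment of goal-directed behavior in a
    virtual apartment. Provides a machine-readable task specification (13
    scenarios, 70 subtasks with any-time, time-based and event-based goals),
    a JSON-Lines event-log format with reader, writer and validator, a replay
    engine that labels action relevance and computes the eight behavioral
    measures (total score, task efficacy, navigation efficacy, controller
    motion, total actions, time- and event-based prospective memory, clock
    checks), an agent-based gameplay simulator generating synthetic cohorts
    from covariate-driven latent traits, and the psychometric evaluation
    pipeline: Cronbach's alpha with bootstrap confidence intervals and
    reduced-scenario scans, univariate and Mahalanobis outlier screening,
    stepwise AIC model selection in three directions, and FDR-corrected
    correlation tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
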