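Package: timestair
Title: Simulation and Analysis of Adaptive Staircase Time-Estimation
    Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for simulating and analysing interval-reproduction
    experiments that manipulate feedback through an asymmetric (weighted
    up/down) staircase on the tolerance window around a 1-second target.
    Provides the trial-wise window-update engine, generative models of
    synthetic responders, assembly of multi-block expectation
    induction/violation designs with the standard exclusion rules, an exact
    Markov forward oracle for the staircase's accuracy dynamics with
    parameter calibration, and the matching statistical pipeline (group
    summaries, mixed-design ANOVA with planned contrasts, Bonferroni post
    hoc mean differences, partial eta squared).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    tools,
    utils,
    yaml
Suggests:
    car,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
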