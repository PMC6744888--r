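Package: endofluct
Title: Endogenous BOLD Fluctuations and Risky Choice: Simulation, Triggering,
    and Decision Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how spontaneous (endogenous) fluctuations in a
    region-of-interest BOLD signal bias risky decision making. Implements a
    real-time activity-triggered trial scheduler based on sliding-window
    percentiles, prospect-theory choice models with an additive gambling-bias
    parameter and their maximum-likelihood fitting and BIC comparison, evoked
    response statistics (percent signal change, cluster-extent permutation
    tests, multilevel mediation), gambling-task design utilities that place
    safe offers at target choice probabilities, and a seeded synthetic-data
    generator that emulates the coupled BOLD/behavioral structure so that
    every stage of the pipeline can be validated by simulation and parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lhs,
    withr
Config/testthat/edition: 3
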