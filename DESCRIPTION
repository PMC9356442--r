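Package: rarsim
Title: Response-Adaptive Randomisation Simulation for Multi-Arm Mortality Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Block-wise simulation of two-arm and four-arm randomised trials
    with a binary 28-day mortality endpoint, calibrated to the stratified
    mortality rates of a large COVID-19 platform trial. Implements fixed
    equal and unequal randomisation alongside response-adaptive strategies
    (a time-tuned probability-of-best rule and a sample-size-discounted
    REMAP-CAP-style rule), at whole-cohort or respiratory-support-subgroup
    scope, with burn-in, outcome-lag and update-cadence scheduling.
    Computes the full operating-characteristics suite across replicated
    trials: expected deaths and allocation proportions at interim cut
    points, power and type-I/familywise error from logistic-model Wald
    tests, relative bias and mean squared error of treatment-effect
    estimates, and Neyman allocation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
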