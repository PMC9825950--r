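Package: gslag
Title: Group Sequential Monitoring of Randomized Trials with Time-Lagged Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Interim monitoring for two-arm randomized clinical trials whose
    primary outcome is ascertained only after a subject-specific time lag, so
    that at an interim analysis the outcome is censored for recently enrolled
    subjects.  Provides censoring-adjusted inverse probability weighted
    complete-case (IPWCC) and covariate-augmented (AIPWCC) treatment-effect
    estimators for continuous, binary, and ordinal outcomes; effective sample
    size and information-fraction accounting; Lan-DeMets alpha-spending
    stopping boundaries (O'Brien-Fleming and Pocock type) with sequential
    power and trial-level monitoring decisions; and synthetic-trial generators
    with staggered enrollment for three benchmark scenarios, together with a
    Monte Carlo driver for operating characteristics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival,
    MASS,
    mvtnorm,
    jsonlite
Config/testthat/edition: 3
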