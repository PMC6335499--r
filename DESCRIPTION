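Package: cohortlife
Title: Abridged Life Tables and Life Expectancy from Cohort Follow-Up Records
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds Chiang abridged (bridge) life tables from individual-level
    retrospective cohort follow-up records: Lexis splitting of person-time
    across age bands, age-specific mortality rates, rate-to-probability
    conversion, life expectancy with Chiang-variance 95% confidence
    intervals, stratified and calendar-period estimates, two-group
    comparisons, years-of-life-lost tallies, and ecological correlations.
    Includes a registry-style synthetic cohort simulator with known
    piecewise-exponential ground truth, analytic and brute-force oracles,
    and an end-to-end pipeline driver, so every stage is testable without
    external data.
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
    optparse
Config/testthat/edition: 3
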