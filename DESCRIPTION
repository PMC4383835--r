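Package: metdiary
Title: Scoring, Simulation and Analysis of 15-Minute Physical Activity Diaries
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for working with 96-slot (15-minute) two-day physical
    activity diaries of the kind collected by web-based time-use surveys.
    Activities are scored against a metabolic-equivalent (MET) compendium;
    per-day and weekday/weekend-weighted metrics (24-hour mean MET,
    MET-hours, moderate-to-vigorous physical activity, category and
    subcategory decompositions) are computed per participant; cohorts are
    compared across residential-area strata with ANOVA, ANCOVA, Tukey HSD,
    chi-square and standardized-coefficient regression. A seeded,
    schedule-level synthetic cohort generator produces diary cohorts whose
    scored marginals match published population summaries, so the whole
    pipeline is testable without access to raw survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    optparse
Config/testthat/edition: 3
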