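Package: recallval
Title: Validation and Cost-Effectiveness Analysis of 24-Hour Dietary Recall Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating interviewer-administered 24-hour dietary
    recall (24HR) surveys against a weighed food record (WFR) benchmark in a
    paired two-arm design, and for costing the competing survey modalities.
    Converts coded consumption records into nutrient intakes through a dietary
    reference bundle (food composition table, standard recipes, portion-size
    conversion factors, FAO/WHO GIFT food groups), applies energy-implausibility
    quality control, and computes group-level equivalence (paired two one-sided
    t tests on log intakes), Bland-Altman agreement, difference-in-differences
    between modalities via a random-intercept mixed model, individual-level
    percentage-error bands, and food-group energy shares. Includes a seeded
    synthetic-data generator with a controllable recall-error structure
    (omissions, intrusions, multiplicative portion-size error, recipe
    substitution, implausible-energy outliers), a Fisher-z sample-size
    calculation for correlation improvement, and an activity- and
    ingredients-based costing module with cost-per-accuracy-point ratios under
    reference-data-borrowing scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    nlme,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
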