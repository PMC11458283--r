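Package: feedeval
Title: Marker-Based Digestibility and Nutrient Retention Analysis for Fish Feeding Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of marker-based (titanium
    dioxide) digestibility and comparative-slaughter nutrient retention
    feeding trials in fish. Computes apparent digestibility coefficients of
    diets from feed/feces marker ratios, back-calculates test-ingredient
    coefficients from reference-diet substitution designs, derives nitrogen
    and lipid productive values from whole-body nutrient balances, normalizes
    traits relative to a reference diet, and runs the branching
    parametric/nonparametric group-comparison workflow typical of replicated
    aquarium trials (Shapiro-Wilk, Levene, t/Welch, ANOVA/Tukey,
    Kruskal-Wallis/Dunn, compact letter displays). A synthetic-trial
    generator with known ground truth makes every estimator testable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
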