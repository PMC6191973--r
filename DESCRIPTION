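Package: maximindesign
Title: Maximin and Optimal Two-Treatment Trial Designs with
    Treatment-Dependent Costs and Outcome Variances
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Plans two-treatment randomized trials with parallel (A/B),
    extended parallel (AA/BB), and AB/BA crossover designs when research
    costs and outcome variances may differ between the treatments.
    Computes optimal allocation ratios and asymptotic variances of the
    treatment and treatment-by-period interaction effect estimators under
    a budget constraint, derives maximin designs that guarantee power over
    plausible ranges of the treatment-specific intraclass correlations,
    calculates required sample sizes with small-sample t-test corrections,
    compares designs by relative efficiency, and verifies planned power by
    Monte Carlo simulation under heteroscedastic linear mixed models.
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
    withr
Config/testthat/edition: 3
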