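Package: pgxauc
Title: Pharmacogenetics-Based Prediction of Axitinib Exposure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for pharmacogenetics-guided dosing of axitinib in advanced
    renal cell carcinoma. Implements sparse-sampling non-compartmental
    pharmacokinetic analysis (trapezoidal AUC over a 12-hour dosing interval,
    total clearance, C-max, C-0hr, trough), a six-locus genotype panel with
    dummy-coded covariates, an exponential regression model of dose-standardized
    AUC with forward variable selection, quartile-based initial-dose advice,
    the association statistics used in exposure-outcome analyses
    (Kruskal-Wallis, Mann-Whitney U, simple linear regression, and a
    Cochran-Armitage trend scan over variants), clinical efficacy and
    adverse-event tabulations, and a seeded synthetic-cohort generator that
    emulates the statistical structure of a sparse-sampling phase II
    pharmacokinetic study for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
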