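Package: dxitools
Title: Diagnostic-Item Grouping and Concurrent Risk Adjustment for Claims Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating concurrent claims-based
    risk-adjustment models on multi-membership diagnostic classifications.
    Provides a diagnosis grouper for ICD-10-CM-shaped code systems in which a
    code may carry up to four overlapping main-effect items plus cross-cutting
    modifiers and numeric scaled variables (with root-stem fallback and
    comparator systems: flat CCSR-like single-membership mappings and HCC-like
    mappings with dominance hierarchies); an enrollee-year cohort builder with
    professional-type diagnosis filtering, annualization, fraction-of-year
    regression weights, newborn handling, top-coding and price deflation;
    sparse age-sex/indicator/scale design matrices; weighted least-squares and
    forward-stepwise estimation with a p-value entry criterion and
    Bonferroni-corrected significance flags; a validation battery with
    weighted R-squared, weighted mean absolute error, a weight-modified
    Cumming prediction measure, predictive ratios by spending percentile, and
    mean residuals binned by diagnostic frequency with patient-clustered
    confidence intervals; and a seeded synthetic claims generator with known
    ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
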