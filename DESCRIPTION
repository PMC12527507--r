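Package: esconvert
Title: Automatic Computation, Conversion and Reconciliation of Effect Sizes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes eleven effect size measures (Cohen's d, Hedges' g, mean
    difference, odds ratio, risk ratio, incidence rate ratio, correlation,
    Fisher's z, variability ratio, coefficient of variation ratio, number
    needed to treat) from any recognized combination of reported statistics in
    a per-study dataset, converts flexibly across measures, selects a main
    estimate when overlapping inputs coexist, quantifies their consistency,
    aggregates dependent effect sizes within clusters, and diffs
    double-extracted datasets for reconciliation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, tools
Suggests: testthat (>= 3.0.0), withr, readxl, metafor, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
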