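Package: screenflow
Title: Simulation and Evaluation of Double-Reading Breast-Screening Workflows with an AI Reader
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate multi-centre breast-screening cohorts and
    evaluate double-reading workflows in which an artificial-intelligence
    system acts as an independent second reader. Implements the standard
    double-reading decision logic (including site-dependent arbitration of
    agreed recalls), the supporting-independent-reader and
    double-reader-triage variants, and an additional-reader flagging proxy.
    Computes cancer detection rate, positive predictive value, recall rate,
    sensitivity, specificity, arbitration rate and reading-workload savings
    with Wilson score confidence intervals, stratified by centre, age,
    breast density and ethnicity, pooled as equally weighted centre means.
    Provides stratified-bootstrap one-sided non-inferiority and gated
    superiority tests against standard double reading, centre-comparison
    chi-squared/ANOVA batteries with Bonferroni-corrected pairwise tests,
    and projection of prospective cancer-detection uplift from the
    standalone interval-cancer flag rate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
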