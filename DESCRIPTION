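Package: rasmct
Title: RAS Pathway Signature Scoring and Mouse Clinical Trial Analysis
    for PDX Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for linking an up/down gene-expression signature of
    RAS/MAPK pathway activation to drug response in patient-derived
    xenograft (PDX) mouse clinical trials. Reads gene signatures (GMT or
    two-column files) and expression matrices (TSV/CSV/GCT), computes
    per-sample signature scores (mean z-scored expression of the Up set
    minus the Down set), derives the tumor-growth-inhibition endpoint
    dT/dC from per-animal tumor-volume time series, and runs the
    genotype-stratified statistical layer (Pearson correlation with
    t-based p-values, Welch's t-test, sign-based contingency counts,
    single-covariate screens). A latent-factor synthetic-cohort
    generator provides ground truth for end-to-end and
    parameter-recovery testing, and a bundled 25-model colorectal-cancer
    PDX cetuximab cohort supports full reproduction of the reference
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
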