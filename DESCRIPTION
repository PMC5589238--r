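Package: allostat
Title: Change-Score Analytics and Dyadic Vulnerability Indexing for
    Social Allostasis Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing pre/post biomarker responses of
    mother-infant dyad cohorts under a chronic foraging-uncertainty
    stressor: per-dyad change scores and the closed-form change-score
    identity linking baseline-delta coupling to printed summary
    statistics, group-versus-individual percent-change ("allostasis
    ratio") contrasts with a permutation null, baseline-split inversion
    analysis with Newman-Keuls post hoc testing, regression-to-the-mean
    diagnostics (Pitman-Morgan test), hierarchical clustering of
    candidate variables, and construction of a composite dyadic
    vulnerability index. Includes a calibrated synthetic cohort
    generator with a latent vulnerability factor for validation and
    power studies, and a reproducible pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
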