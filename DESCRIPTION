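Package: twinset
Title: Co-Twin Control Methylation Analysis with Gene-Set Truncated Product Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Matched-pair epigenetic association analysis for monozygotic twin
    cohorts. Computes intra-pair differences in CpG methylation, glucose traits
    (HOMA-IR, fasting glucose, HbA1c) and covariates, runs single-CpG matched
    ordinary least squares scans with Benjamini-Hochberg false discovery rate
    control, and tests the joint effect of CpGs per gene and across a gene set
    with the (weighted) truncated product method, using either its analytic
    independence null or a correlation-preserving sign-flip permutation null.
    Includes a seeded synthetic twin-cohort generator with block-correlated
    methylation, pair-shared variance, covariates and plantable linear effects,
    so the whole pipeline is testable end to end without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
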