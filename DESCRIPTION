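Package: ptcRiskScreen
Title: Screening of Lymph-Node Metastasis Risk Genes in Papillary Thyroid
    Carcinoma from Multi-Cohort Expression Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Reusable implementation of a screening funnel for papillary
    thyroid carcinoma (PTC) lymph-node-metastasis risk genes: per-cohort
    differential expression under fold-change and p-value gates,
    direction-consistent multi-cohort intersection, Kaplan-Meier / log-rank
    survival filtering with expression dichotomization, a correlation-bin
    cumulative score that ranks core risk genes, and 2^-ddCt RT-qPCR
    relative quantification with paired testing. Ships a seeded
    synthetic-cohort generator with planted truth (differential genes, a
    correlated core module, hazard-linked survival, paired Ct tables) so
    the whole funnel can be exercised and calibrated end to end without
    external cohort downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    optparse,
    survival,
    testthat (>= 3.0.0),
    withr
biocViews: GeneExpression, DifferentialExpression, Survival, Microarray
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
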