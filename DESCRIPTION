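Package: mirPopCor
Title: Population-Correlation Selection of Prognostic and Chemopredictive
    miRNAs via Cancer-Registry Linkage
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Links a small tumor expression cohort to a large cancer-registry
    cohort through composite tumor-progression groups (T, N, M stage and
    grade) to screen miRNAs for prognostic and chemopredictive value.
    Implements the three-layer selection rule (cohort Cox and Kaplan-Meier
    cutoff scan, group-level linear regression of registry restricted mean
    survival on cohort group-mean expression, and population-level Cox and
    Kaplan-Meier re-evaluation after group-mean imputation), claims-based
    treatment-flag derivation and treatment strata, cell-line drug-response
    trichotomization and regression validation, and CRISPR/RNAi dependency
    screening analytics. A synthetic-data module generates registry, cohort,
    claims, cell-panel and dependency inputs with known planted structure so
    the full pipeline is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    survival,
    S4Vectors,
    SummarizedExperiment,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
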