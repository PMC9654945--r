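Package: GrowthSense
Title: Primary Growth-Model Fitting and Electronic Sensor Fusion for
    Predictive Microbiology
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Fits the four classical primary bacterial growth models
    (modified Gompertz, logistic, Huang, Baranyi-Roberts) to plate-count
    log series and to electronic-nose/electronic-tongue sensor responses
    by multi-start bounded nonlinear least squares, with
    degrees-of-freedom-adjusted R-squared and RMSE and train/test
    validation. Screens sensor channels with one-way ANOVA reconstructed
    exactly from per-time summary statistics, Duncan's multiple range
    test with homogeneous-subset letters, and Pearson correlation with
    significance stars; fuses the two sensor arrays through
    variance-weighted principal-component scores; and inverts fitted
    curves to predict shelf life from a log-count threshold. Includes a
    seeded synthetic-data generator that reproduces the replicate
    structure of a cold-storage juice spoilage study so the whole
    pipeline is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    lhs,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'growth-models.R'
    'model-fitting.R'
    'panel.R'
    'sensor-selection.R'
    'fusion.R'
    'tables.R'
    'synthetic-data.R'
    'pipeline.R'
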