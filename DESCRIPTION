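Package: DrugStimScreen
Title: Drug-Microenvironment Perturbation Screens: Simulation and Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for combinatorial ex vivo viability screens in
    which primary tumour samples are exposed to drugs, microenvironmental
    stimuli, and their combinations on 384-well plates. Provides plate-wise
    normalization of luminescence readouts against interior DMSO controls,
    robust z-scaling, consensus clustering of stimulus-response profiles,
    a no-intercept linear interaction model classifying drug-stimulus
    interactions into synergistic and antagonistic categories, bootstrap
    stability-selection lasso for genetic determinants, a read-ratio
    trisomy-12 caller for ATAC peak counts, and survival analyses including
    maximally selected rank statistics. A fully parameterised synthetic-screen
    generator with known ground truth supports end-to-end validation of every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    glmnet,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse,
    yaml,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
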