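Package: cordMediate
Title: Mediation Analysis of Prenatal Arsenic Exposure, Cord Blood Gene
    Expression and Birth Weight
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for linking low-level prenatal arsenic exposure measured
    in cord blood to birth anthropometric outcomes through cord blood gene
    expression. Implements limit-of-detection substitution and extreme-group
    exposure classification on the log scale, small-for-gestational-age
    derivation from sex-specific reference growth curves, gestational-age
    adjusted birth weight ratios, covariate selection and interquartile-range
    scaled regression effects with formal model diagnostics, single-channel
    microarray preprocessing (quantile normalization, replicate collapsing,
    reliability filtering), a sex-stratified dual-contrast quadrant screen
    for candidate mediator transcripts, the classical Baron-Kenny four-model
    mediation cascade with interaction handling and sensitivity analyses,
    and qPCR confirmation utilities (reference-gene stability, multi-reference
    relative quantification, platform concordance). A synthetic mother-newborn
    cohort generator with a planted mediator gene provides a ground-truth
    test bed for the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    limma,
    lmtest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
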