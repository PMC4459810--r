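Package: ivfsem
Title: Integrated Visual Fields and Structural Equation Models for Falls
    Risk in Glaucoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the relationship between visual function and
    falls in primary open-angle glaucoma. Builds binocular integrated visual
    fields (IVF) from monocular Humphrey 24-2 total-deviation grids by the
    best-sensitivity rule, summarises them into regional mean total
    deviations, runs the univariate faller/non-faller comparison battery
    (chi-square, Fisher's exact, Welch t), and fits latent-variable
    structural equation models linking glaucomatous damage and systemic
    covariates to falls and injurious falls, with maximum-likelihood
    estimation, RMSEA/CFI fit indices and Wald confidence intervals
    implemented from first principles. A seeded synthetic-cohort generator
    reproduces the study's latent-factor structure so every pipeline stage
    is testable without patient data.
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
    optparse
Config/testthat/edition: 3
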