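Package: iequant
Title: Ionization-Efficiency-Based Quantification for PFAS Suspect Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Standard-free semi-quantification of per- and polyfluoroalkyl
    substances (PFAS) detected by suspect screening in negative-mode
    LC-ESI-HRMS, and the organofluorine mass-balance accounting it serves.
    Provides molecular-formula and isotope-pattern arithmetic, a target
    compound registry with homologue-series discovery, response-factor
    calibration with 1/concentration weighting and relative-residual
    linearity checks, anchoring of lab-specific response factors onto a
    transferable relative log ionization-efficiency (IE) scale, a
    gradient-boosted log IE regression model trained with chemical-grouped
    cross-validation, conversion of predicted IE to measurement-specific
    response factors through an in-run calibrant bridge, homologue-series
    quantification, fluorine-equivalent conversion with blank/LOQ handling
    and unidentified extractable organofluorine (UEOF) fractions, suspect
    evidence checks with Schymanski-style confidence levels, and seeded
    synthetic-data generators for every stage of the workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineOB,
    ChemmineR,
    jsonlite,
    stats,
    utils,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
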