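Package: vamsquant
Title: Quantification and Validation of Capillary Microsampling Hormone Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data-processing pipeline for targeted LC-MS hormone assays run on
    volumetric absorptive microsampling (VAMS) devices. Implements the
    whole-blood two-compartment model that converts total dried-blood
    concentrations to serum equivalents using analyte-specific
    plasma-to-red-blood-cell partition ratios and the sample hematocrit;
    internal-standard area-ratio calibration with run-level blank correction
    and linearity diagnostics; the bioanalytical method-validation battery
    (intra/interday imprecision, accuracy, limit of quantification,
    extraction recovery, matrix effects, carryover, hematocrit robustness,
    storage stability) with pass/fail evaluation against configurable FDA-style
    thresholds; Bland-Altman agreement analysis of paired serum and capillary
    measurements with confidence intervals and paired significance tests; and a
    seeded measurement simulator that generates every input the pipeline
    consumes for verification and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse,
    withr
Config/testthat/edition: 3
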