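Package: structgamma
Title: Structure-Based Gamma Evaluation for Radiotherapy Dose QA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Patient-specific quality assurance of radiotherapy dose
    distributions by structure-based ("structural") gamma evaluation.
    Reads DICOM RT Dose and RT Structure Set objects, rasterises each
    contoured structure onto the dose grid, masks the reference and
    evaluated dose volumes per structure, and computes the 3D gamma index
    with organ-specific dose-difference normalisation: global maximum
    dose, local dose, QUANTEC organ-at-risk tolerances, or
    clinician-specified tolerance doses.  Produces signed gamma maps,
    per-structure pass rates, and aggregate summaries, and includes a
    synthetic phantom generator with analytically known gamma behaviour
    for end-to-end verification.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    readr,
    rlang,
    scales,
    stats,
    tibble,
    tidyr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
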