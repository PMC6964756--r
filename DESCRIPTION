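Package: icondose
Title: Independent Point-Dose Verification for Gamma Knife Radiosurgery Plans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An independent secondary point-dose calculation engine for
    Leksell Gamma Knife Icon-style stereotactic radiosurgery, intended for
    plan quality assurance. Models the 192-source, eight-sector unit
    geometry with per-beamlet rotation for nonstandard gamma angles,
    renders the patient skull either by voxel-image thresholding or from
    24 scalar radius measurements, ray traces each beamlet for
    radiological depth, and computes point dose with an
    exponential-attenuation (tissue-maximum-ratio style) model. Includes
    the nonparametric agreement statistics used to audit a cohort of
    paired primary/secondary calculations (Wilcoxon signed-rank,
    Mann-Whitney U, Kendall tau-b), synthetic voxel phantoms and plan/cohort
    generators with closed-form oracles, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    tidyr,
    ggplot2,
    rlang,
    generics,
    jsonlite,
    RNifti,
    readr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
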