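Package: drsquant
Title: Quantitative Diffuse Reflectance Spectroscopy of Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-model-based quantification of tissue diffuse reflectance
    spectra in the 500-600 nm hemoglobin band. Provides a white
    (absorption-rescaled) Monte Carlo photon-transport kernel for fiber-optic
    probe geometries, hemoglobin absorption with a vessel pigment-packing
    correction, self-calibration arithmetic against a Spectralon reflectance
    standard, bounded nonlinear least-squares inversion for hemoglobin oxygen
    saturation (SO2), total hemoglobin (THb) and reduced scattering, a
    contact-pressure measurement gate, a random-intercept linear mixed-effects
    comparison stage, and a synthetic cohort generator emulating a
    repeated-measures optical biopsy study design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    nlme,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
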