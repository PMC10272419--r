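Package: turbispec
Title: Spectral Analysis of Glucose and Scattering Confounders in Turbid Media
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how glucose, dissolved ions, scatterer density
    and scatterer size each perturb the near-infrared (1000-1700 nm) diffuse
    reflectance of a turbid medium such as a 3% Intralipid phantom. Implements
    the Graaff power-law approximation to Mie theory for the reduced scattering
    coefficient and its analytic sensitivities, semi-infinite diffusion-theory
    reflectance with the differential-absorbance route to effective-attenuation
    coefficient (EAC) difference spectra, a seeded photon Monte Carlo engine
    with correlated-sampling perturbation runs, and a pipeline that extracts
    the spectral features separating the glucose signal from its scattering
    confounders.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
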