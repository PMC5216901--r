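Package: psitrap
Title: Global Kinetic and Compositional Analysis of Photosystem I Supercomplexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize the function and composition of Photosystem I
    light-harvesting supercomplexes (PSI-LHC) from time-resolved and steady-state
    spectroscopy, density-gradient proteomics and pigment chromatography.
    Implements global (shared-lifetime) variable-projection fitting of streak-camera
    fluorescence images with Gaussian instrument response, sequential compartment
    models with decay-/evolution-associated spectra conversion, the amplitude-weighted
    average time to charge separation, second-derivative absorption band detection,
    per-fraction label-free intensity normalization with enrichment calls, and
    response-factor-corrected pigment stoichiometry. A synthetic-data module
    generates all inputs with the statistical structure these analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    deSolve,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
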