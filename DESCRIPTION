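Package: apoastab
Title: Thermal-Shift Screening and Biophysical Validation Analytics for
    Apolipoprotein A-I Structure Correctors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for small-molecule structure-corrector
    screening against a thermodynamically destabilized apolipoprotein A-I
    variant. Provides differential scanning fluorimetry melt-curve
    processing (Savitzky-Golay smoothing, negative first derivative,
    apparent-Tm calling with quality flags), primary-screen hit selection
    against wild-type reference curves, an ANS fluorescence-ratio
    orthogonal screen with significance testing, two-state unfolding
    thermodynamics (Boltzmann sigmoid fits, van't Hoff enthalpy, linear
    extrapolation method free energies from chemical denaturation),
    one-site EC50 fitting of Tm dose-response and isothermal titration
    calorimetry data, macrophage viability and ABCA1-mediated cholesterol
    efflux statistics, and synthetic assay-data generators so the whole
    pipeline runs and is tested without instrument exports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    minpack.lm,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
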