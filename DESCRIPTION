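Package: phototox
Title: Quantitative Phototoxicity Assessment from Label-Free Live-Cell Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify light-induced stress in adherent cell cultures
    from brightfield time-lapse microscopy. Implements a frame-differencing
    cellular-activity metric with its normalisation and contrast-enhancement
    chain, mitotic-rounding timing distributions and their peaks, cell-size
    based mother/daughter population dynamics, division versus cell-cycle
    arrest event classification, viability-dye quantification, and
    illumination-dose bookkeeping for widefield and point-scanning regimes.
    Includes a synthetic time-lapse generator with ground truth so that every
    analysis stage can be exercised end to end without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
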