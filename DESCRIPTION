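Package: gelprot
Title: Differential Spot Analysis and Protein Identification for Two-Dimensional Gels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-style toolkit for two-dimensional gel electrophoresis
    (2-DE) proteomics of low-volume samples such as muscle microdialysate.
    Quantifies spots on gel images as background-corrected integrated optical
    density, normalizes per-gel intensities to parts-per-million (ppm),
    classifies proteins as differentially expressed under a fold-change rule,
    and compares differential sets across conditions. A companion
    identification layer computes theoretical protein mass and isoelectric
    point, performs in-silico tryptic digestion, matches peptide-mass
    fingerprints within a ppm tolerance, and applies tandem-MS
    identification criteria. Includes a synthetic gel simulator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    tiff,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
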