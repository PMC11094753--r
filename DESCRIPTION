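Package: stromules
Title: Geometry of Plastid-Stromule Interaction Capacity in a Quasi-2D Cytoplasm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the spatial capacity of plant plastids to interact with
    other organelles in the thin (quasi-2D) cortical cytoplasm of epidermal
    cells. Plastid bodies are discs and stromules are polyline segments;
    pixel-grid distance fields give the "interaction region" (area within a
    proximity d of the plastid boundary) and angular raytracing gives
    "plastid access" (fraction of directions from a point that encounter
    plastid material within a reach D). Includes closed-form 2D/3D
    interaction-region formulas under membrane or volume conservation,
    grid scans over plastid-pair separation and stromule branch angle,
    maximum-likelihood fits of stromule morphology statistics (Poisson
    counts, log-normal lengths, power-law plastid density), and a seeded
    synthetic-data generator emulating measured stromule statistics in
    stressed and unstressed leaf tissue.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    fitdistrplus,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
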