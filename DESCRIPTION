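Package: widefilm
Title: Wide-Angular-Tolerance Thin-Film Optical Filter Design and
    Spectral Imaging Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Transfer-matrix simulation of multilayer dielectric thin-film
    stacks with exact analytic gradients of transmittance with respect to
    layer thicknesses, dual-angle merit functions for designing band-pass
    filters whose transmittance is stable between normal and oblique
    incidence, and an application pipeline that synthesizes RGB images
    from hyperspectral cubes through a filter plus camera-spectral-response
    model and scores near-color crop segmentation under transmittance-curve
    swapping. Includes a fully seeded synthetic-data generator (target
    curves, known-truth stacks, two-class pepper/leaf scenes) and a small
    encoder-decoder segmenter so the whole pipeline runs without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
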