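Package: veinflow
Title: Coupled Xylem-Phloem Transport on Procedural Leaf Vein Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic simulator of steady-state water and sucrose transport in
    angiosperm leaves. Generates reticulate five-order vein networks on a lattice for
    parameterised leaf shapes and second-order vein angles, assembles the coupled
    Darcy/osmotic/advection-diffusion balance equations for xylem pressure, phloem
    pressure and phloem sucrose concentration at every node, solves the nonlinear
    steady state with a damped sparse Newton method, and computes whole-leaf
    transport-efficiency indices (area-average pressures and concentrations, vein-angle
    response curves, distribution maps, and the xylem-phloem pressure-difference
    circulation diagnostic).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    readr,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
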