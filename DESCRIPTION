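Package: bctsim
Title: Multiscale Finite-Element Simulation of Breast-Conserving Surgery
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A multiscale mechano-biological finite-element simulator of
    breast-conserving surgery. Couples an explicit reaction-diffusion solver
    for a five-species wound-healing and angiogenesis model (cell density,
    mitosis-regulating chemical, capillary density, oxygen level and
    macrophage-derived growth factor) with a quasi-static Total-Lagrangian
    hyperelastic solver (Mooney-Rivlin tissue, Veronda-Westmann skin membrane,
    fibroblast active traction, damage-scaled strain energy) on labelled
    tetrahedral meshes. Provides synthetic breast phantom generation, Gmsh MSH
    input, VTU/STL/PLY output, virtual cylindrical resection, gravity-pose and
    unloaded-configuration estimation, and cosmetic-outcome evaluation by
    rigid surface alignment and surface-distance statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    withr,
    xml2
Config/testthat/edition: 3
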