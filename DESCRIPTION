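Package: callusim
Title: Voxel Finite-Element Simulation of Initial Fracture-Callus Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the initial (primary) phase of fracture-callus
    formation in long bones on a growing voxel mesh. Mesenchymal stem cell
    and chondrocyte concentrations are propagated by Fick diffusion, solved
    with trilinear hexahedral finite elements and implicit time stepping.
    Element faces whose concentrations exceed trigger thresholds grow at a
    velocity given by a normalized sigmoid law, and a free mesh-growth
    algorithm adds callus elements on the integer lattice without a
    pre-meshed callus domain. Includes idealized diaphyseal geometries with
    transverse, oblique and comminuted fracture presets, bridging and
    gap-closure metrics, VTK export and labeled-volume import.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    utils,
    tools
Suggests:
    RNifti,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
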