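Package: morphomech
Title: Mechanics of Self-Organized 2D-to-3D Morphogenesis in Growing Cell Sheets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying and modelling the mechanical self-organization
    of growing multilayered tissues. Implements a shear-lag model of the radial
    compression gradient generated by interfacial shear stress between a growing
    epithelial sheet and its substrate, with an energy-based delamination
    criterion predicting the critical colony size for 2D-to-3D stratification;
    segmentation-derived per-cell compressive strain fields; tissue-fluidity
    metrics (cell shape index with the vertex-model jamming threshold,
    cross-correlation particle image velocimetry, drift-subtracted rms
    velocity); mitotic spindle orientation and division-symmetry analysis;
    detection of T1 transitions and rosettes from junction topology; and a
    discrete axisymmetric growth simulator with Coulomb interfacial friction
    and Maxwell stress relaxation that reproduces the solid-like/3D versus
    fluid-like/2D morphogenetic dichotomy. Ships synthetic-data generators with
    ground truth for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
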