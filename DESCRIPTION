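Package: microedr
Title: Processing of Micro-Electron-Diffraction (MicroED) Tilt Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for processing still-image electron-diffraction tilt
    series collected from three-dimensional protein microcrystals
    (MicroED). Covers beam-center determination from Friedel pairs,
    reconstruction of three-dimensional reciprocal-space vectors with an
    Ewald-sphere curvature correction, unit-cell length estimation from
    pairwise distance distributions, unit-cell basis-vector determination
    by difference-vector clustering, still-pattern spot prediction and
    Miller indexing with a Laue-zone threshold, iterative spot refinement
    by mass centering and contrast filtering, background-subtracted
    intensity integration, and merging of symmetry-equivalent reflections
    under point group 422 into a text reflection file. Includes a
    synthetic tilt-series simulator that renders ground-truth diffraction
    patterns for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
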