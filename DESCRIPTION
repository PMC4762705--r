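Package: gnathometry
Title: Accuracy Assessment of 3D-Planned Bimaxillary Orthognathic Surgery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies, per osteotomized jaw segment, the rigid-body
    discrepancy between a 3D virtual orthognathic plan and the
    postoperative outcome. Segments are tracked by virtual triangles of
    cephalometric landmarks; rigid Procrustes fits between states are
    decomposed in the natural-head-position anatomical frame into
    clinically oriented translations (anterior/posterior, left/right,
    up/down) and rotations (pitch, roll, yaw). Includes rigid
    intensity-based volume registration and trimmed-ICP surface
    registration stand-ins, cohort summary tables, observer-reliability
    statistics (absolute variation with bootstrap confidence intervals,
    two-way random-effects absolute-agreement intraclass correlation),
    and a deterministic synthetic skull-phantom generator.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    RNifti
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
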