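Package: toposcreen
Title: Quality Control and Curation Pipeline for TopoChip High-Content Imaging Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the post-acquisition data architecture of TopoChip
    high-content imaging screens: chip layout and tile-naming grammar,
    z-stack projection and grid cropping, per-cell derived features
    (form factor, nucleus-to-cytoplasm ratio, radial actin fraction),
    per-unit aggregation and coefficient-of-variation stability analysis,
    three-tier quality control with full ledger accounting, an
    Anderson-Darling plus signal-to-noise replicate-consistency filter,
    and surface ranking with nested stratified splits.  A synthetic-screen
    generator emulates the statistical structure of a real screen
    (density classes, variance decomposition, planted artifacts) so the
    whole pipeline is testable without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    tiff,
    EBImage,
    yaml,
    jsonlite,
    rhdf5
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
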