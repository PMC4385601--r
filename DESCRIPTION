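Package: cervicell
Title: Morphometric Quantification and Rule-Based Grading of Cervical
    Squamous Epithelial Cells
Version: 0.1.0
Authors@R:
    person("cervicell", "maintainers", email = "maintainers@cervicell.dev",
           role = c("aut", "cre"))
Description: Quantifies morphological and chromatic descriptors of
    segmented cervical squamous epithelial cells (nucleus area and
    nucleus-to-cytoplasm ratio relative to a normal reference,
    circularity, solidity, a radial boundary shape signature, and
    per-compartment RGB staining strength), applies an ordered set of
    five pathology-motivated criteria to flag abnormal cells, grades
    flagged cells into the Bethesda-system categories LSIL, HSIL and
    SCC, and clusters per-feature values with affinity propagation to
    derive exemplar cells and data-driven threshold suggestions.
    Includes a synthetic stained-cell image generator with exact ground
    truth so the full pipeline is testable without clinical material,
    and a command-line interface covering simulation, feature
    extraction, detection, grading, clustering and evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    optparse,
    png,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
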