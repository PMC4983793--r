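Package: FLIPimage
Title: Bead-Based Quantification of Fluorescence Immunoprecipitation Images
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of fluorescence immunoprecipitation (FLIP) micrographs:
    agarose beads captured after an IP are segmented, non-spherical
    contaminants and bead clumps are rejected by shape filtering, and each
    bead is scored as the difference between the mean fluorescence of its
    perimeter rim and of its body. Image-level signals are averaged per bead,
    corrected against a matched IgG-control image, and summarised with
    duplicate-measurement variability. The package also provides a synthetic
    bead-image simulator with exact ground truth, recombinant-YFP
    standard-curve calibration of lysate fluorescence with assay-planning
    rules, the legacy whole-image mean-fluorescence readout, and screening
    reports that relate FLIP signals to immunoblot-derived IP efficiency.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    EBImage,
    tiff,
    jsonlite,
    mgcv
Suggests:
    testthat (>= 3.0.0),
    optparse
biocViews: Software, CellBasedAssays, Proteomics, Visualization
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'FLIPimage-package.R'
    'beadseg.R'
    'calibration.R'
    'flipsignal.R'
    'io.R'
    'pipeline.R'
    'screening.R'
    'synthbeads.R'
    'utils.R'
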