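Package: extrafib
Title: Partitioning of Bone Mineral Between Collagen Fibrils and
    Extrafibrillar Mineral Structures
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying how much of the hydroxyapatite in
    cortical bone lies outside the collagen fibrils. Implements a
    rectangular unit-cell model of the mineralized collagen ultrastructure
    (gap and overlap zones, vertical inter-fibril mineral stacks, and
    over/underlying mineral plates), an area-weighted count-partition
    estimator that converts energy-dispersive X-ray (EDXS) calcium count
    rates from overlap-zone, gap-zone and mineral-structure regions into
    the extrafibrillar mineral fraction, and a voxel-based synthetic
    ultrastructure simulator with known ground truth for validating the
    estimator and the associated image measurements (D-period, plate
    thickness, lane spacing, fibril cross-section ellipses) and
    diffraction-texture statistics (00l arc extent and visibility).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    yaml,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
biocViews: ElectronMicroscopy, ImageAnalysis, Software
RoxygenNote: 7.3.3
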