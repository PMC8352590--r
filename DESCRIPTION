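Package: CortexQuant
Title: Cortical Enrichment, Asymmetry and Filopodia Quantification for
    Single-Cell Fluorescence Micrographs
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the cortical localization of fluorescently tagged
    proteins in single amoeboid cells: cortex-to-cytoplasm intensity ratios
    measured in a thin peripheral band, cortical asymmetry as the standard
    deviation of intensity around the cell periphery, filopodium counting by
    a radial tip search, pixel-wise two-channel colocalization
    (cytofluorograms), linescan profiles averaged with restricted cubic
    splines, and the accompanying statistical layer (ROUT outlier exclusion,
    one-way ANOVA with Tukey or Dunnett comparisons). Includes a synthetic
    micrograph generator with full ground truth so that every stage of the
    pipeline can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    EBImage,
    tiff,
    jsonlite,
    yaml,
    splines,
    withr,
    multcomp
Suggests:
    testthat (>= 3.0.0),
    optparse
biocViews: CellBiology, Visualization, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
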