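Package: chipcsf
Title: Simulation and Analysis of Chipcytometry Immunophenotyping for CSF Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for iterative slide-based
    cytometry (Chipcytometry) of cerebrospinal fluid leukocytes. A synthetic
    data generator emulates CSF cellularity, centrifugation cell loss, chip
    loading, and iterative stain-image-bleach cycles with autofluorescence,
    illumination inhomogeneity, and cell detachment. Downstream stages provide
    virtual image rendering and cell detection, bleach-subtraction background
    correction, cross-cycle track matching with artificial-phenotype quality
    control, hierarchical gating into CSF immune populations, light-chain
    clonality assessment, chip cell-density sufficiency reporting, and
    Bland-Altman method agreement against reference measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    EBImage,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    pheatmap,
    yaml
Config/testthat/edition: 3
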