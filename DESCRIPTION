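Package: noduleTME
Title: Spatial and Single-Cell Quantification of Preinvasive and Invasive
    Lung-Nodule Microenvironments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification toolkit for dissecting the tumor microenvironment
    of part-solid lung nodules across matched normal (NL), non-solid (NS,
    preinvasive) and solid (S, invasive) compartments. Implements detection of
    B cell-endothelium-T cell (BET) triads from segmented imaging mass
    cytometry cell tables, 100-micrometre neighborhood density analysis,
    tertiary lymphoid structure (TLS) densities and activation/exhaustion
    ratios, bin-matched gene-module scoring with AT2-like versus club-like
    tumor cell-of-origin assignment, arm-level squared-CNV cell scores with
    tumor-cluster calling, spot-level spatial-significance and rank-recovery
    signature scoring with cell-type coexistence correlation, the single-cell
    QC filters and marker-co-expression doublet rule, and the paired
    nonparametric comparison layer. A synthetic-data generator with recorded
    ground truth exercises every stage end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
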