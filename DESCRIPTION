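Package: protean
Title: Experimental-Null Calibrated Discovery of Altered Proteins in
    Label-Free Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for ion-current-based label-free quantitative proteomics
    of multi-group designs: rollup of peptide-level intensity tables to
    protein level (dataset-wide median normalization, outlier-peptide
    removal, ion-current aggregation), case-versus-control differential
    testing with an experimental-null calibration of the false
    altered-protein discovery rate (FADR) across fold-change thresholds,
    three-way classification of altered proteins into sustained,
    drug-induced and drug-unique expression patterns by hierarchical
    clustering of fold-of-significance z-scores, and dataset-level
    reporting (PCA of ratio vectors, pairwise R-squared, set overlaps,
    volcano exports).  Includes a synthetic-data generator emulating a
    4-group x 2-tissue animal study so the whole pipeline is testable
    without raw mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
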