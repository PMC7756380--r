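Package: epimapr
Title: Linear Epitope Mapping and Sero-Diagnostics for Peptide Tiling Microarrays
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for linear B-cell epitope mapping with
    overlapping-peptide tiling microarrays probed with patient sera.
    Covers probe-set design from mature antigen sequences, spot-level
    fluorescence import, log2 signal-to-noise statistics with robust
    z-score normalization against blank spots, contiguity-based epitope
    calling, classification of epitopes as surface-exposed from
    solvent-accessible surface area of a 3D structure, and a diagnostic
    layer (EAST classes, sIgE/sIgG4 ratios, sensitivity and specificity,
    Mann-Whitney group comparison, PCA variable contributions). Includes
    a synthetic cohort generator so the whole pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    pheatmap,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
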