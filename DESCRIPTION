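Package: mxclust
Title: Hierarchical Clustering and Merging of Multi-Crystal Diffraction Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Selects which partial diffraction datasets to merge in
    multi-crystal and serial macromolecular crystallography. Computes
    non-isomorphism distances between unmerged reflection wedges (either the
    intensity-correlation distance sqrt(1 - cc^2) or the maximal unit-cell
    edge variation), builds an average-linkage dendrogram, estimates the
    merging threshold automatically (largest-cluster growth, or the minimal
    threshold reaching a completeness target), merges the selected clusters by
    inverse-variance weighting in the asymmetric unit, and reports the
    standard data-quality statistics (completeness, multiplicity, CC1/2,
    Rmerge, Rmeas, Rpim, mean I/sigma(I), sigAno) overall and per resolution
    shell. Includes readers for unmerged XDS-ASCII reflection files, a
    synthetic wedge generator for controlled experiments, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
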