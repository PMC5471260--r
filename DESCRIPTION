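Package: radsem
Title: Linking Radiologist Semantic Scores to Computed Radiomic Features in CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for studying how radiologist-scored
    semantic features of lung tumors (cavitation, air bronchogram,
    calcification, texture, border definition, contour, lobulation,
    spiculation, concavity) relate to quantitative radiomic features computed
    from CT volumes. Provides 3D radiomic feature extraction (shape,
    first-order statistics, gray-level co-occurrence, size-zone and run-length
    texture families) on original, Laplacian-of-Gaussian filtered and
    stationary-wavelet sub-band images; Spearman-correlation redundancy
    pruning; an association engine combining folded ROC AUC with Noether's
    test for binary scores and Spearman correlation with Kruskal-Wallis tests
    for ordinal scores, with Benjamini-Hochberg false-discovery-rate control;
    and a seeded synthetic CT tumor-phantom generator whose morphology is
    driven by the nine semantic scores.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    igraph,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
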