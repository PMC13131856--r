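Package: UDIPalign
Title: Multimodal Momentum-Contrast Imaging Phenotypes and Cross-Modal
    Alignment Genetics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Self-supervised multimodal representation learning for paired
    volumetric images (symmetric momentum contrast with cross-modal positive
    pairs, FIFO negative queues and an InfoNCE objective), extraction of
    unsupervised-learning-derived imaging phenotypes (UDIPs) by joint PCA of
    frozen-encoder patch embeddings with per-entry outlier QC, feature-level
    cross-modal alignment metrics (linear CKA with bootstrap/permutation
    null, CCA with canonical-correlation summaries), a miniature
    imaging-genetics pipeline (OLS association scans, minP aggregation,
    LD/distance clumping, padded interval-tree locus overlap), phenome-wide
    UDIP-trait association utilities, and a synthetic multimodal
    imaging-genetics cohort generator with known ground truth for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    RNifti,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: ImagingMS, DimensionReduction, GenomeWideAssociation,
    FeatureExtraction, Software
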