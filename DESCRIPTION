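Package: ConsensusEmbed
Title: Consensus Embedding of High-Dimensional Biomedical Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Ensemble dimensionality reduction by consensus embedding:
    many base low-dimensional embeddings are generated from bootstrapped
    feature subspaces, scored with triplet-preservation and clustering
    statistics, filtered for strength, and fused by combining their
    normalized pairwise-distance matrices with a maximum-likelihood
    (median or mean) estimator before a final multidimensional-scaling
    projection. Includes per-pixel Haralick and first-order texture
    features for grayscale images, t-statistic feature pruning,
    mean-shift object sub-sampling for large pixel sets, replicated
    k-means and hierarchical clustering evaluators, and synthetic
    generators (two-region RGB images, two-tissue phantoms with noise
    and bias fields, two-class expression matrices) emulating the
    framework's study conditions.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, grDevices, Rcpp, jsonlite, withr, png, class
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse, tiff, RNifti
Config/testthat/edition: 3
biocViews: DimensionReduction, Clustering, Classification, Software
NeedsCompilation: yes
RoxygenNote: 7.3.3
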