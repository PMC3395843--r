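# ConsensusEmbed

Ensemble dimensionality reduction for noisy, high-dimensional biomedical
data: pixel-level texture maps from MR-like images and sample-level
expression matrices. A single projection — PCA or spectral graph embedding
(GE) — is easily derailed by noise in the feature space. `ConsensusEmbed`
builds a *consensus embedding* instead: it generates many base embeddings
from bootstrapped feature subspaces, scores them, keeps the strong ones,
and fuses them into one stable low-dimensional representation.

## The method

Given an R × N feature matrix **F**:

1. **Generate** — draw M feature subsets η₁…η_M of V < N features each
   (every feature covered at least once) and embed each `X_m = Φ(F[, η_m])`
   into ℝⁿ, Φ ∈ {GE, PCA}. GE solves the normalized-cut generalized
   eigenproblem `(D − A)x = λDx` with Gaussian affinity
   `A(i,j) = exp(−‖F(c_i) − F(c_j)‖₂ / σ)`.
2. **Select** — score each base embedding with an embedding-strength
   measure ψ: exactly, the fraction of object triplets whose closest pair
   in feature space stays closest in the embedding; practically, the
   cluster-overlap classification accuracy (labels available) or the
   R-squared cluster-validity index (unsupervised). Keep embeddings with
   ψ above a threshold θ derived from the best score.
3. **Combine** — compute each survivor's pairwise Euclidean distance
   matrix, scale it to unit maximum, take the elementwise **median** (or
   mean) across the stack, and project the fused matrix W̃ back to
   coordinates with classical multidimensional scaling.

The supporting theory is implemented and numerically verified: the
binomial success probability of an ensemble of strong embeddings
(`consensusSuccessProbability`, `1 − (1−α)^M`), the Jensen bound showing
the mean-combined consensus never has higher pairwise-distance error than
its average member (`prop2Check`), and the monotone link between embedding
strength and triplet-level classification accuracy (`tripletAccuracy`).

For images, per-pixel features are 14 windowed GLCM Haralick statistics
(`haralickPerPixel`, compiled) plus optional first-order window statistics;
large pixel sets are reduced to Gaussian mean-shift modes first
(`consEmbedMS`) and the consensus coordinates are mapped back to every
pixel. Synthetic generators reproduce the framework's study conditions:
two-tissue phantoms with noise and multiplicative bias fields
(`makePhantom`), a two-region RGB toy image with chromatic noise
(`makeToyRGB`), and two-class expression matrices (`makeExpression`).

## Worked example

```r
library(ConsensusEmbed)

ex     <- makeExpression(seed = 1)              # 100 samples x 100 features
pruned <- tStatPrune(ex$features, 30)$features  # top 30 by |Welch t|
pruned
#> FeatureSet: 100 objects x 30 features; labeled (50 positive)

cfg <- consensusConfig(drMethod = "pca", n = 4, M = 100,
                       clusterer = "hclust", seed = 1)
res <- consensusEmbed(pruned, cfg)
res$consensus
#> ConsensusResult: 100 objects in 4 dims from 18 selected embeddings; stress = 0.3483

part <- hierarchicalCluster(coords(res$consensus), 2)
clusterAccuracy(clusterLabels(part), objectLabels(pruned))
#> [1] 0.93
```

Of 100 PCA base embeddings of 5-feature subspaces, 18 scored within 15% of
the best cluster-overlap accuracy (θ = 0.714) and were fused; Ward-linkage
clustering of the 4-D consensus embedding recovers the two classes with
0.93 accuracy (the same clusterer on the 30-feature pruned space directly
reaches 0.90). A command-line wrapper over the same functions (subcommands
`synth`, `segment`, `eval`, `sweep`) is at
`inst/scripts/consensus-embed.R`.

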