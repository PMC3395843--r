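---
title: "Consensus embedding: model, parameters, and design choices"
author: "ConsensusEmbed maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus embedding: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

High-dimensional object descriptions — per-pixel texture vectors from an MR
image, per-sample expression profiles — are routinely projected to a few
dimensions before clustering or classification. A single projection, linear
(PCA) or non-linear (graph embedding), is sensitive to noise: one corrupted
direction in feature space can dominate the affinity structure and destroy
class separation in the embedding.

Consensus embedding treats dimensionality reduction the way random forests
treat classification. From an $R \times N$ feature matrix it draws $M$
bootstrapped feature subsets of $V < N$ features each (every feature covered
by at least one subset), embeds each subset into $\mathbb{R}^n$ with the
base DR method $\Phi \in \{\mathrm{GE}, \mathrm{PCA}\}$, scores each base
embedding, keeps the strong ones, and fuses the survivors through their
pairwise-distance matrices: each selected embedding's Euclidean distance
matrix is scaled to unit maximum, corresponding entries are combined across
the stack with a maximum-likelihood estimator $\Omega$ (elementwise median
by default, mean optionally), and the fused matrix $\tilde W$ is projected
back to coordinates with classical multidimensional scaling.

The quality currency throughout is the *triangle relationship*: for a
triplet of objects $(c,d,e)$, the indicator $\Delta(c,d,e) = 1$ iff the
strictly closest pair in the source space is still the strictly closest
pair in the embedding. The *embedding strength* $\psi^{ES}$ is the fraction
of the $Z = \binom{R}{3}$ unique triplets preserved. Three results justify
the construction, and all three are verified numerically by the test suite:

* if each of $M$ independent strong embeddings preserves a triplet with
  probability $\alpha$, the probability that the ensemble preserves it is
  $\sum_{K=1}^{M}\binom{M}{K}\alpha^K(1-\alpha)^{M-K} = 1-(1-\alpha)^M$,
  monotone in both arguments (`consensusSuccessProbability`);
* the mean-combined consensus distance matrix never has a higher mean
  squared error against a reference than the average error of its members —
  a convexity (Jensen) argument, checked on random stacks (`prop2Check`);
* $\psi^{ES} \ge \phi \cdot U/Z$, where $\phi$ is the fraction of *class
  triplets* (labels not all equal, $U = Z - Y$ of them) whose same-label
  pair stays strictly closest: embedding strength grows monotonically with
  triplet-level classification accuracy, which licenses the practical
  surrogates below (`tripletAccuracy`, `countClassTriplets`).

Exact $\psi^{ES}$ enumeration is $O(R^3)$ and infeasible for pixel data, so
the pipeline scores embeddings with surrogates: the **supervised** surrogate
clusters the embedded objects (replicated $k$-means, $T = 2$) and takes the
cluster-overlap classification accuracy
$\max_t (D_{TP} + D_{TN})/|S^+ \cup S^-|$; the **unsupervised** surrogate is
the R-squared index $(SST - SSW)/SST$ of the clustering. `embeddingStrength`
itself switches to seeded uniform triplet sampling above
`maxExactR = 200` objects; at $5\times10^4$ sampled triplets the sampling
error is below 0.01 (property-tested).

## Strong-embedding selection

Selection keeps embeddings with strength above a threshold $\theta$
derived from the best observed strength. Two readings of the published
rule $\theta = 0.15 \times \max_m \psi_m$ are exposed:

* `"factor-of-max"` — the literal rule. With strengths in, say,
  $[0.5, 0.96]$, $\theta \approx 0.14$ selects *every* embedding. A
  consensus built this way inherits the weak majority — exactly the failure
  mode the theory's necessity condition (a consensus of weak embeddings is
  weak) predicts, and what we observe: on a texture phantom the
  literal rule yields 0.63 pixel accuracy where selective fusion reaches
  0.96.
* `"within-of-max"` — keep embeddings within 15% of the best
  ($\theta = 0.85 \max_m \psi_m$). This is the reading under which
  selection performs its theoretical role, and it is the pipeline default.
  `selEmbed()` itself documents the literal rule as its default so the
  algorithmic surface matches the published description; `consensusConfig()`
  flips to `"within-of-max"`.

## Tunable parameters

| parameter | default | units / range | rationale |
|---|---|---|---|
| `M` | 40 (pipeline), 200 for expression studies | count | accuracy varies little with `M` (verified: range < 0.05 across `M` ∈ {50, 100, 200}); 40 keeps desk-scale image sweeps tractable |
| `V` | `max(2, round(sqrt(N)))` | features | random-forest-style subspace size; the source never states one |
| `n` | 3 (images), 4 (expression), 1 (toy) | dims | matches the target dimensionalities of the emulated studies; `estimateIntrinsicDim()` (variance-explained PCA, threshold 0.95, capped at `N-1`) when unknown |
| `thetaFactor` | 0.15 | fraction | see selection discussion |
| `estimator` | median | — | robust to a corrupted member; mean exposed for the comparison study |
| `geBandwidth` | mean pairwise distance | distance | affinity $A_{ij} = \exp(-\lVert F_i - F_j\rVert_2/\sigma)$; scale-free default |
| `bandwidth` (mean shift) | Silverman-style $(4/((d+2)R))^{1/(d+4)}$ | z-scored units | features are z-scored inside mean shift so the bandwidth is scale-free |
| `window`, `grayLevels` | 5, 64 | pixels, levels | standard Haralick practice; offsets {(0,1),(1,0),(1,1),(1,−1)}, symmetric GLCM, statistics averaged over offsets |
| `standardize` | `TRUE` | — | see below |

**Standardization.** Haralick features span orders of magnitude (energy
$\le 1$, sum variance in the thousands), and unscaled Euclidean affinities
are dominated by whichever column is largest. The pipeline therefore
z-scores feature columns before subspace embedding. The toy-image study is
the documented exception: RGB channels are already commensurate, and
per-channel z-scoring would amplify the noise-free R channel into easy
separability for *every* method, hiding the failure mode the study
illustrates — its config sets `standardize = FALSE`.

## Mean-shift sub-sampling

Embedding $10^4$ pixels directly means $10^4$-order eigenproblems per base
embedding. `consEmbedMS` first replaces objects by the modes of a
Gaussian-kernel mean shift over the z-scored features (plain mean shift;
trajectories iterate until the shift falls below $10^{-4}h$ or 300
iterations; coinciding trajectories are pooled as they merge, which cannot
change fixed points; kernel weights below $e^{-12}$ are truncated, a
relative error under $10^{-5}$ on each local mean; modes closer than $h/2$
are merged). Every original object inherits its mode's consensus
coordinates through the saved assignment map, and the number of
representatives is determined by the density, not preset. When labels
exist, representative labels are the majority vote of their members, and
embedding strength at representative level is computed with *weights* equal
to member counts — weighted accuracy at representative level is identical
to mapped-back pixel accuracy, which keeps selection honest when
representatives carry very different numbers of pixels. If the mode count
exceeds `maxReps` (default 400) the bandwidth is escalated by factors of
1.3; the final bandwidth is recorded.

## What the synthetic generators emulate

`makePhantom` emulates a two-tissue proton-density-like slice: per-pixel
class mean $\times$ a smooth positive multiplicative bias field (a
normalized off-center 2-D Gaussian surface rescaled to mean 1 and
peak-to-mean deviation `biasPct`/100 — the source describes only "smooth
multiplicative inhomogeneity", so any such surface qualifies) plus Gaussian
noise with sd = `noisePct`/100 of the mean noiseless intensity
(noise-relative-to-mean convention). Levels are restricted to the study
grid {0, 1, 3, 5, 7, 9}% × {0, 20, 40}% unless overridden. The default
geometry (an off-center disc of one tissue inside the other, 64 × 64) gives
both classes contiguous regions with a curved interface. What it does *not*
emulate: real anatomy, within-tissue texture, partial-volume mixing. The
consequence is visible in the sweep: with flat tissues the only
class-separating texture signal is the local mean intensity, so at 20–40%
bias the task becomes intrinsically hard for every method, and the
comparison at those cells is between near-baseline methods — the relevant
claim there is only that consensus GE is not worse than single GE.

`makeToyRGB` emulates the two-region RGB scenario: classes share G and B
means and differ in R by 60 gray levels; i.i.d. Gaussian noise (sd 40)
corrupts G and B only. The noise level is chosen by a margin analysis done
before any acceptance measurement: a 2-means split of raw RGB is captured
by chromatic noise when $\sigma > 37.5$ (the noise split's within-cluster
sum of squares drops below the class split's), while the R-bearing 2-D
subspaces remain individually recoverable roughly while
$\sigma\sqrt{2} < \Delta_R$, i.e. $\sigma \lesssim 42$. The default
$\sigma = 40$ sits inside that window: raw k-means and full-space GE fail,
the {R,G}/{R,B} subspaces are (stochastically) recoverable, and only the
selective consensus succeeds reliably. The toy comparison runs at full
pixel level on a 30 × 30 image so that every base embedding is a dense
eigenproblem and no method benefits from mean-shift denoising.

`makeExpression` generates two-class Gaussian expression-like data:
`nInformative` (10) features shifted by `effectSize` (1.0 standardized
units — a strong but realistic univariate effect for cancer signatures)
among `nNoise` (90) class-independent features, 50 samples per class,
column order shuffled. It emulates mean-shifted signatures only: no
correlation structure, no heteroscedasticity, no batch effects — passing
tests show robustness of the ensemble machinery, not performance on real
cohorts.

## Evaluation machinery

Evaluation clusterers are intentionally un-tuned. "Replicated" k-means is
made reproducible by spawning one child seed per random restart from a
master seed and keeping the lowest-inertia partition; its inertia is
non-increasing in the number of replicates by construction. Hierarchical
clustering defaults to Ward linkage: average linkage — a plausible
alternative — splits off 1–2 outlier samples when the tree is cut at
$T = 2$ (observed accuracy ≈ 0.5 on data whose k-means accuracy is ≈ 0.95),
so it cannot serve as an evaluation clusterer at small $T$; the linkage
remains configurable. The random-subspace kNN ensemble (`knnSubspaceEnsemble`)
is the no-DR comparator: one `class::knn` vote per feature subset, vote
fractions averaged.

## Numerical choices and degenerate inputs

* Eigen-sign convention: the largest-magnitude loading/coordinate of every
  axis is made positive, so embeddings are reproducible across platforms.
* Classical MDS clips negative eigenvalues to zero and zero-pads (with a
  warning) when fewer than `n` positive eigenvalues exist; the fused
  matrix enters the double-centering squared, the standard Torgerson form.
* Haralick statistics on a degenerate (constant) window: correlation and
  both information measures of correlation are defined as 0; sum variance
  is centered on the sum average; gray tones are 1-based; logs are natural.
* A zero-variance feature with distinct class means gets $|t| = \infty$
  and ranks first in `tStatPrune` (it separates the classes perfectly).
* Triplet ties: when the high-dimensional anchor is tied, a triplet counts
  as preserved iff no strict high-dimensional inequality is violated in the
  embedding — exact isometries of symmetric configurations keep
  $\psi^{ES} = 1$.
* An all-zero distance matrix is returned unchanged from normalization
  (with a warning); an all-identical point set has RSI defined as 0.
* The stress of the final MDS fit (normalized residual between $\tilde W$
  and the embedded distances) is always reported, because the consensus is
  defined on the distance matrix, not on any particular projection of it.

## Problem sizes of the shipped studies

The package's own studies are desk-scale: 64 × 64 phantoms over the full
18-cell noise × bias grid with 3 phantoms per cell and $M = 40$; a 30 × 30
toy image over 10 noise seeds with $M = 12$; expression matrices of
100 samples × 100 features pruned to 30, $M \in \{50, 100, 200\}$, 3
replicate datasets per $M$. These sizes were chosen so a complete
replication runs on a laptop in minutes while preserving each study's
qualitative contrast; the emulated publications used full BrainWeb volumes,
clinical prostate MRI, and four public expression cohorts, none of which
ship with this package.

## Known limitations

* No out-of-sample extension: new objects cannot be embedded without
  rerunning the pipeline (inherent to the distance-matrix formulation).
* The mean-shift map is the accuracy ceiling of every sub-sampled run; at
  strong bias levels mode purity drops and all methods are capped alike.
* Multi-class (> 2) triplet accuracy and cluster-validity measures beyond
  RSI are out of scope.
* The feature-subspace generator is the only base-embedding diversification
  implemented; parameter-perturbation ensembles are not.

## A worked example

```{r example}
library(ConsensusEmbed)

ex <- makeExpression(seed = 1)                 # 100 x 100, labels attached
pruned <- tStatPrune(ex$features, 30)$features # top 30 by |Welch t|
cfg <- consensusConfig(drMethod = "pca", n = 4, M = 100,
                       clusterer = "hclust", seed = 1)
res <- consensusEmbed(pruned, cfg)
res$consensus                                  # show(): stress, K, dims
part <- hierarchicalCluster(coords(res$consensus), 2)
clusterAccuracy(clusterLabels(part), objectLabels(pruned))
```
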