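# Triplet-preservation theory: the triangle relationship, embedding strength,
# class triplets, and the strong-embedding selection step.

# vectorized triangle relationship on n x 3 matrices of the three pairwise
# values (cd, ce, de) in the high- and low-dimensional spaces
.triPreserved <- function(hi, lo) {
  mn <- pmin(hi[, 1], hi[, 2], hi[, 3])
  nmin <- (hi[, 1] == mn) + (hi[, 2] == mn) + (hi[, 3] == mn)
  out <- logical(nrow(hi))
  u <- nmin == 1L                       # strict anchor: Defn-1 inequalities
  if (any(u)) {
    w1 <- u & hi[, 1] == mn
    w2 <- u & hi[, 2] == mn
    w3 <- u & hi[, 3] == mn
    out[w1] <- lo[w1, 1] < lo[w1, 2] & lo[w1, 1] < lo[w1, 3]
    out[w2] <- lo[w2, 2] < lo[w2, 1] & lo[w2, 2] < lo[w2, 3]
    out[w3] <- lo[w3, 3] < lo[w3, 1] & lo[w3, 3] < lo[w3, 2]
  }
  t <- !u                               # tied anchor: every strict high-d
  if (any(t)) {                         # inequality must survive strictly
    ok <- rep(TRUE, sum(t))
    ht <- hi[t, , drop = FALSE]; lt <- lo[t, , drop = FALSE]
    for (a in 1:3) for (b in 1:3) if (a != b) {
      viol <- ht[, a] < ht[, b] & lt[, a] >= lt[, b]
      ok <- ok & !viol
    }
    out[t] <- ok
  }
  out
}

#' Triangle relationship of one triplet
#'
#' Indicator that the strictly closest pair of a triplet in the
#' high-dimensional space is still the strictly closest pair in the embedding.
#' When the high-dimensional minimum is tied, the triplet counts as preserved
#' iff no strict high-dimensional inequality among the three pairwise values
#' is violated in the embedding (so exact isometries of symmetric
#' configurations score 1).
#'
#' @param hi numeric(3): pairwise values (cd, ce, de) in the source space.
#' @param lo numeric(3): the same pairwise values in the embedding.
#' @return 0 or 1.
#' @examples
#' triangleRelationship(c(1, 2, 3), c(10, 20, 30))  # 1
#' triangleRelationship(c(1, 2, 3), c(3, 2, 1))     # 0
#' @export
triangleRelationship <- function(hi, lo) {
  stopifnot(length(hi) == 3, length(lo) == 3, all(hi >= 0), all(lo >= 0))
  as.integer(.triPreserved(matrix(hi, 1), matrix(lo, 1)))
}

# all i<j<k index triples as an n x 3 matrix
.allTriplets <- function(R) t(utils::combn(R, 3))

# n x 3 matrix of the three pairwise squared... (plain Euclidean) distances
# for given triplet indices, computed without forming a full R x R matrix
.tripletDists <- function(X, trip) {
  d <- function(i, j) sqrt(rowSums((X[i, , drop = FALSE] -
                                    X[j, , drop = FALSE])^2))
  cbind(d(trip[, 1], trip[, 2]), d(trip[, 1], trip[, 3]),
        d(trip[, 2], trip[, 3]))
}

.sampleTriplets <- function(R, size, seed) {
  .withSeed(seed, {
    trip <- cbind(sample.int(R, size, replace = TRUE),
                  sample.int(R, size, replace = TRUE),
                  sample.int(R, size, replace = TRUE))
    bad <- trip[, 1] == trip[, 2] | trip[, 1] == trip[, 3] |
           trip[, 2] == trip[, 3]
    while (any(bad)) {
      n <- sum(bad)
      trip[bad, ] <- cbind(sample.int(R, n, TRUE), sample.int(R, n, TRUE),
                           sample.int(R, n, TRUE))
      bad <- trip[, 1] == trip[, 2] | trip[, 1] == trip[, 3] |
             trip[, 2] == trip[, 3]
    }
    trip
  })
}

#' Embedding strength from triplet preservation
#'
#' The fraction of unique object triplets whose triangle relationship is
#' preserved from the source space to the embedding (Euclidean metric in
#' both). All C(R,3) triplets are enumerated when \code{R <= maxExactR};
#' beyond that a seeded uniform sample of triplets is scored instead.
#'
#' @param xHi source-space objects: \linkS4class{FeatureSet} or matrix.
#' @param xLo the embedding of the same objects.
#' @param maxExactR largest R for exact enumeration (default 200).
#' @param sampleSize triplets to sample when enumeration is skipped.
#' @param seed seed for triplet sampling.
#' @return A \linkS4class{TripletStats}.
#' @examples
#' X <- matrix(rnorm(30), 10, 3)
#' strength(embeddingStrength(X, X))  # identity embedding: exactly 1
#' @export
embeddingStrength <- function(xHi, xLo, maxExactR = 200, sampleSize = 50000,
                              seed = 1) {
  Xh <- .mat(xHi); Xl <- .mat(xLo)
  R <- nrow(Xh)
  if (R < 3) stop("need at least 3 objects to form a triplet")
  if (nrow(Xl) != R) stop("object counts differ between spaces")
  exact <- R <= maxExactR
  trip <- if (exact) .allTriplets(R) else .sampleTriplets(R, sampleSize, seed)
  pres <- .triPreserved(.tripletDists(Xh, trip), .tripletDists(Xl, trip))
  new("TripletStats",
      Z = if (exact) choose(R, 3) else as.numeric(nrow(trip)),
      preserved = sum(pres), psi = mean(pres), sampled = !exact,
      sampleSize = if (exact) integer(0) else as.integer(sampleSize),
      seed = if (exact) integer(0) else as.integer(seed))
}

#' Count class and non-class triplets
#'
#' For binary class sizes n1, n2: Z = C(n1+n2, 3) unique triplets, of which
#' Y = C(n1, 3) + C(n2, 3) are label-homogeneous (non-class) and U = Z - Y
#' are class triplets.
#'
#' @param n1,n2 class sizes (n1 + n2 >= 3).
#' @return Named numeric vector with elements Z, Y, U.
#' @examples
#' countClassTriplets(3, 3)  # Z = 20, Y = 2, U = 18
#' @export
countClassTriplets <- function(n1, n2) {
  if (n1 < 0 || n2 < 0) stop("class sizes must be nonnegative")
  if (n1 + n2 < 3) stop("need at least 3 objects")
  Z <- choose(n1 + n2, 3)
  Y <- choose(n1, 3) + choose(n2, 3)
  c(Z = Z, Y = Y, U = Z - Y)
}

#' Triplet-level classification accuracy of an embedding
#'
#' Scores every class triplet (three objects whose labels are not all equal):
#' its anchor is the one same-label pair, and the triplet counts as correctly
#' represented when that pair is strictly the closest of the three in the
#' embedding. The fraction of such triplets is the triplet-level
#' classification accuracy.
#'
#' @param xLo the embedding (\linkS4class{Embedding} or matrix).
#' @param labels binary (0/1) labels, one per object, both classes present.
#' @return A \linkS4class{ClassTripletStats}.
#' @export
tripletAccuracy <- function(xLo, labels) {
  Xl <- .mat(xLo)
  labels <- as.integer(labels)
  R <- nrow(Xl)
  if (length(labels) != R) stop("one label per object required")
  n1 <- sum(labels == labels[1])
  if (n1 == R) stop("all objects share one class; no class triplets exist")
  trip <- .allTriplets(R)
  l <- cbind(labels[trip[, 1]], labels[trip[, 2]], labels[trip[, 3]])
  cls <- !(l[, 1] == l[, 2] & l[, 2] == l[, 3])
  trip <- trip[cls, , drop = FALSE]
  l <- l[cls, , drop = FALSE]
  lo <- .tripletDists(Xl, trip)
  # anchor column: 1 = (c,d), 2 = (c,e), 3 = (d,e) — the same-label pair
  anchor <- ifelse(l[, 1] == l[, 2], 1L, ifelse(l[, 1] == l[, 3], 2L, 3L))
  pres <- logical(nrow(trip))
  for (a in 1:3) {
    w <- anchor == a
    o <- setdiff(1:3, a)
    pres[w] <- lo[w, a] < lo[w, o[1]] & lo[w, a] < lo[w, o[2]]
  }
  cnt <- countClassTriplets(n1, R - n1)
  new("ClassTripletStats", Z = cnt[["Z"]], U = cnt[["U"]], Y = cnt[["Y"]],
      preservedL = sum(pres), phiAccTriplet = mean(pres))
}

#' Cluster-overlap classification accuracy
#'
#' For each cluster t, counts true positives (members of the positive class
#' inside the cluster) and true negatives (negative-class objects outside
#' it), divides by the object count, and returns the maximum over clusters —
#' the accuracy of the cluster showing the greatest overlap with the positive
#' class.
#'
#' @param clusters integer cluster ids, one per object.
#' @param truth binary (0/1) ground-truth labels.
#' @param weights optional nonnegative object weights (e.g. the number of
#'   original objects each mean-shift representative stands for); weighted
#'   accuracy at representative level equals the accuracy of the mapped-back
#'   full-resolution partition.
#' @return Accuracy in [0, 1].
#' @export
clusterAccuracy <- function(clusters, truth, weights = NULL) {
  truth <- as.integer(truth)
  stopifnot(length(clusters) == length(truth))
  if (is.null(weights)) weights <- rep(1, length(truth))
  W <- sum(weights)
  acc <- vapply(unique(clusters), function(t) {
    inC <- clusters == t
    (sum(weights[inC][truth[inC] == 1L]) +
     sum(weights[!inC][truth[!inC] == 0L])) / W
  }, numeric(1))
  max(acc)
}

#' Supervised embedding-strength surrogate
#'
#' Clusters the embedded objects into \code{k} groups with an unsupervised
#' clusterer and returns the cluster-overlap classification accuracy against
#' the given labels; used in place of exact triplet enumeration when labels
#' are available.
#'
#' @param xLo embedding coordinates.
#' @param labels binary (0/1) labels.
#' @param k number of clusters (default 2).
#' @param clusterer function (coords, k) -> \linkS4class{Partition}; default
#'   replicated k-means.
#' @param seed seed forwarded to the default clusterer.
#' @param weights optional object weights, see \code{\link{clusterAccuracy}}.
#' @return Accuracy in [0, 1].
#' @export
supervisedStrength <- function(xLo, labels, k = 2,
                               clusterer = NULL, seed = 1, weights = NULL) {
  X <- .mat(xLo)
  if (is.null(clusterer))
    clusterer <- function(x, k) replicatedKMeans(x, k, seed = seed)
  p <- clusterer(X, k)
  clusterAccuracy(clusterLabels(p), labels, weights = weights)
}

#' Unsupervised embedding-strength surrogate (R-squared index)
#'
#' Clusters the embedded objects into \code{k} groups, then computes
#' RSI = (SST - SSW) / SST where SST is the total sum of squared deviations
#' from the grand mean (per dimension) and SSW the pooled within-cluster sum
#' of squares. 0 means no cluster structure; values near 1 mean tight,
#' well-separated clusters.
#'
#' @inheritParams supervisedStrength
#' @return RSI in [0, 1].
#' @export
unsupervisedStrength <- function(xLo, k = 2, clusterer = NULL, seed = 1) {
  X <- .mat(xLo)
  if (nrow(X) < k) stop("need at least k objects")
  if (is.null(clusterer))
    clusterer <- function(x, k) replicatedKMeans(x, k, seed = seed)
  p <- clusterer(X, k)
  rsIndex(X, clusterLabels(p))
}

#' R-squared index of a given partition
#'
#' @param x coordinates (objects in rows).
#' @param clusters integer cluster ids.
#' @return (SST - SSW)/SST, with 0 (and a warning) when SST = 0.
#' @export
rsIndex <- function(x, clusters) {
  X <- .mat(x)
  sst <- sum(scale(X, center = TRUE, scale = FALSE)^2)
  if (sst <= .Machine$double.eps) {
    warning("all objects identical (SST = 0); RSI defined as 0")
    return(0)
  }
  ssw <- 0
  for (t in unique(clusters)) {
    Xi <- X[clusters == t, , drop = FALSE]
    ssw <- ssw + sum(scale(Xi, center = TRUE, scale = FALSE)^2)
  }
  (sst - ssw) / sst
}

#' Select strong embeddings (SelEmbed)
#'
#' Scores every base embedding with a strength function and keeps those whose
#' strength exceeds the threshold \eqn{\theta}. Two threshold modes are
#' offered: \code{"factor-of-max"} sets \eqn{\theta = factor \times \max_m
#' \psi_m} (the literal reading of the published selection rule), while
#' \code{"within-of-max"} sets \eqn{\theta = (1 - factor) \times \max_m
#' \psi_m} (keep embeddings within \code{factor} of the best).
#'
#' @param embeddings list of \linkS4class{Embedding}.
#' @param strengths optional numeric vector of precomputed strengths; when
#'   NULL, \code{strengthFn} is applied to each embedding.
#' @param strengthFn function Embedding -> numeric strength.
#' @param thetaMode threshold mode, see above.
#' @param thetaFactor numeric factor (default 0.15).
#' @return List with elements \code{embeddings} (selected, strength slot
#'   filled), \code{Q} (selected indices, order preserved), \code{psi} (all
#'   strengths) and \code{theta}.
#' @export
selEmbed <- function(embeddings, strengths = NULL, strengthFn = NULL,
                     thetaMode = c("factor-of-max", "within-of-max"),
                     thetaFactor = 0.15) {
  thetaMode <- match.arg(thetaMode)
  if (!length(embeddings)) stop("no embeddings supplied")
  if (is.null(strengths)) {
    if (is.null(strengthFn))
      stop("supply either 'strengths' or 'strengthFn'")
    strengths <- vapply(embeddings, strengthFn, numeric(1))
  }
  if (length(strengths) != length(embeddings))
    stop("one strength per embedding required")
  mx <- max(strengths)
  theta <- switch(thetaMode,
                  "factor-of-max" = thetaFactor * mx,
                  "within-of-max" = (1 - thetaFactor) * mx)
  Q <- which(strengths > theta)
  if (!length(Q))
    stop("no embedding exceeds theta = ", signif(theta, 4),
         "; lower 'thetaFactor' (too few selected embeddings make the ",
         "consensus unreliable)")
  sel <- lapply(Q, function(m) {
    e <- embeddings[[m]]
    e@strength <- strengths[m]
    e@id <- as.integer(m)
    e
  })
  list(embeddings = sel, Q = Q, psi = strengths, theta = theta)
}
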