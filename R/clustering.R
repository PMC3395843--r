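# Unsupervised evaluators: replicated k-means, hierarchical clustering, the
# random-subspace kNN ensemble comparator, and label-map rendering.

.ssw <- function(X, labels) {
  s <- 0
  for (t in unique(labels)) {
    Xi <- X[labels == t, , drop = FALSE]
    s <- s + sum(scale(Xi, center = TRUE, scale = FALSE)^2)
  }
  s
}

#' Replicated k-means clustering
#'
#' Runs k-means from \code{replicates} seeded random initializations and
#' returns the partition with the lowest within-cluster sum of squares, so
#' the result is fully reproducible given the master seed. When the data
#' hold at most k distinct rows the exact partition by distinct value is
#' returned directly.
#'
#' @param x coordinates (objects in rows); matrix, \linkS4class{FeatureSet}
#'   or \linkS4class{Embedding}.
#' @param k number of clusters (<= R).
#' @param replicates number of random restarts (default 25).
#' @param seed master seed spawning one child seed per replicate.
#' @return A \linkS4class{Partition}.
#' @export
replicatedKMeans <- function(x, k, replicates = 25, seed = 1) {
  X <- .mat(x)
  R <- nrow(X)
  if (k > R) stop("'k' exceeds the number of objects")
  if (k == 1) {
    return(new("Partition", labels = rep(1L, R), k = 1L,
               inertia = sum(scale(X, center = TRUE, scale = FALSE)^2),
               accuracy = numeric(0)))
  }
  uu <- unique(X)
  if (nrow(uu) <= k) {
    key <- do.call(paste, c(as.data.frame(X), sep = "\r"))
    lab <- as.integer(factor(key, levels = unique(key)))
    return(new("Partition", labels = lab, k = as.integer(max(lab)),
               inertia = .ssw(X, lab), accuracy = numeric(0)))
  }
  seeds <- .childSeeds(seed, replicates)
  best <- NULL
  for (s in seeds) {
    km <- .withSeed(s, tryCatch(
      stats::kmeans(X, centers = k, iter.max = 100, nstart = 1),
      error = function(e) NULL))
    if (is.null(km)) next
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  if (is.null(best)) stop("k-means failed on every replicate")
  new("Partition", labels = as.integer(best$cluster), k = as.integer(k),
      inertia = best$tot.withinss, accuracy = numeric(0))
}

#' Agglomerative hierarchical clustering cut to k clusters
#'
#' Euclidean distances with Ward linkage ("ward.D2") by default:
#' variance-minimizing merges yield balanced clusters when the tree is cut
#' at small k, whereas average linkage tends to split off outlier
#' singletons. Deterministic.
#'
#' @inheritParams replicatedKMeans
#' @param linkage linkage criterion passed to \code{\link[stats]{hclust}}.
#' @return A \linkS4class{Partition}.
#' @export
hierarchicalCluster <- function(x, k, linkage = "ward.D2") {
  X <- .mat(x)
  if (k > nrow(X)) stop("'k' exceeds the number of objects")
  hc <- stats::hclust(stats::dist(X), method = linkage)
  lab <- as.integer(stats::cutree(hc, k = k))
  new("Partition", labels = lab, k = as.integer(k), inertia = .ssw(X, lab),
      accuracy = numeric(0))
}

#' Random-subspace kNN ensemble classifier
#'
#' Trains one kNN vote on each feature subset of the plan (no dimensionality
#' reduction) and averages the per-subset positive-class vote fractions into
#' an ensemble probability; an object is called positive when its averaged
#' probability exceeds 0.5.
#'
#' @param train labeled \linkS4class{FeatureSet}.
#' @param test \linkS4class{FeatureSet} or matrix over the same features.
#' @param plan \linkS4class{SubsetPlan} over the shared feature space.
#' @param k neighbors per vote (default 5; must not exceed the training size).
#' @return List with \code{probability} (per test object) and \code{class}
#'   (0/1).
#' @export
knnSubspaceEnsemble <- function(train, test, plan, k = 5) {
  Xtr <- .mat(train); ytr <- .labels(train); Xte <- .mat(test)
  if (!length(ytr)) stop("training labels required")
  if (k > nrow(Xtr)) stop("'k' exceeds the training size")
  if (plan@N != ncol(Xtr)) stop("plan does not match the feature space")
  probs <- vapply(plan@subsets, function(sub) {
    pred <- class::knn(Xtr[, sub, drop = FALSE], Xte[, sub, drop = FALSE],
                       cl = factor(ytr, levels = c(0, 1)), k = k, prob = TRUE)
    pwin <- attr(pred, "prob")
    ifelse(pred == "1", pwin, 1 - pwin)
  }, numeric(nrow(Xte)))
  probs <- matrix(probs, nrow = nrow(Xte))
  p <- rowMeans(probs)
  list(probability = p, class = as.integer(p > 0.5))
}

.labelPalette <- c("#E41A1C", "#4DAF4A", "#377EB8", "#FF7F00", "#984EA3",
                   "#FFFF33", "#A65628", "#F781BF", "#999999")

#' Render a partition of pixels as an RGB label image
#'
#' Assigns each cluster id a deterministic color and lays the labels back
#' onto the image grid (column-major order, matching the per-pixel feature
#' extractors).
#'
#' @param partition a \linkS4class{Partition} (or integer label vector).
#' @param imageShape \code{c(height, width)} with
#'   \code{height * width == R}.
#' @return List with \code{image} (H x W x 3 array in [0, 1]) and
#'   \code{legend} (data.frame of cluster id and color).
#' @export
renderLabelMap <- function(partition, imageShape) {
  lab <- if (is(partition, "Partition")) partition@labels else
    as.integer(partition)
  H <- imageShape[1]; W <- imageShape[2]
  if (H * W != length(lab)) stop("image shape does not match the label count")
  ids <- sort(unique(lab))
  cols <- rep_len(.labelPalette, length(ids))
  rgb <- grDevices::col2rgb(cols) / 255
  img <- array(0, c(H, W, 3))
  idx <- match(lab, ids)
  for (ch in 1:3)
    img[, , ch] <- matrix(rgb[ch, idx], H, W)
  list(image = img, legend = data.frame(cluster = ids, color = cols))
}
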