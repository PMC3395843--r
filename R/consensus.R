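# Consensus construction: distance stacks, normalization, ML combination,
# final MDS projection, and the closed-form/inequality oracles that justify
# the construction.

#' Euclidean pairwise-distance matrix of an embedding
#'
#' Only the upper triangle is computed and then mirrored (the matrix is
#' symmetric with a zero diagonal).
#'
#' @param x \linkS4class{Embedding}, \linkS4class{FeatureSet} or matrix.
#' @return Symmetric R x R matrix of Euclidean distances.
#' @export
pairwiseDistances <- function(x) {
  X <- .mat(x)
  if (nrow(X) == 1) return(matrix(0, 1, 1))
  unname(as.matrix(stats::dist(X)))
}

#' Scale a distance matrix to unit maximum
#'
#' Divides by the largest entry so matrices from different feature subspaces
#' become scale-commensurate before combination. An all-zero matrix is
#' returned unchanged with a warning.
#'
#' @param W symmetric nonnegative matrix.
#' @return W / max(W).
#' @export
normalizeDistances <- function(W) {
  mx <- max(W)
  if (mx <= 0) {
    warning("all-zero distance matrix; returned unchanged")
    return(W)
  }
  W / mx
}

#' Combine a stack of distance matrices with an ML estimator
#'
#' Elementwise median (default; robust to a corrupted member) or mean across
#' the K matrices.
#'
#' @param matrices list of K equally-shaped matrices.
#' @param estimator "median" or "mean".
#' @return The combined matrix.
#' @export
mlCombine <- function(matrices, estimator = c("median", "mean")) {
  estimator <- match.arg(estimator)
  if (!length(matrices)) stop("empty stack")
  dims <- vapply(matrices, dim, integer(2))
  if (any(dims != dims[1])) stop("matrices differ in shape")
  K <- length(matrices)
  if (K == 1) return(matrices[[1]])
  arr <- matrix(unlist(matrices, use.names = FALSE), ncol = K)
  comb <- if (estimator == "mean") rowMeans(arr) else
    as.vector(.rowMediansCpp(arr))
  matrix(comb, dims[1, 1], dims[2, 1])
}

#' Build the consensus embedding from selected embeddings (CalcConsEmbed)
#'
#' For each selected embedding the Euclidean pairwise-distance matrix is
#' computed and scaled to unit maximum; corresponding entries across the
#' stack are fused with the ML estimator (median or mean); and the projection
#' method \eqn{\gamma} (classical MDS by default) embeds the fused matrix in
#' n dimensions. The normalized residual (stress) between the fused matrix
#' and the distances of the projected embedding is reported, since the
#' consensus is defined on the distance matrix, not the projection.
#'
#' @param selected list of \linkS4class{Embedding} over the same objects.
#' @param n target dimensionality of the consensus embedding.
#' @param estimator "median" (default) or "mean".
#' @param gamma projection function (distanceMatrix, n) -> Embedding.
#' @return A \linkS4class{ConsensusResult}.
#' @export
calcConsEmbed <- function(selected, n, estimator = c("median", "mean"),
                          gamma = classicalMDS) {
  estimator <- match.arg(estimator)
  if (!length(selected)) stop("need at least one selected embedding")
  Rs <- vapply(selected, function(e) nrow(.mat(e)), integer(1))
  if (any(Rs != Rs[1])) stop("embeddings cover different object sets")
  Wk <- lapply(selected, function(e) normalizeDistances(pairwiseDistances(e)))
  Wtilde <- mlCombine(Wk, estimator)
  emb <- gamma(Wtilde, n)
  Dfit <- pairwiseDistances(emb)
  up <- upper.tri(Wtilde)
  denom <- sum(Wtilde[up]^2)
  stress <- if (denom > 0) sqrt(sum((Wtilde[up] - Dfit[up])^2) / denom) else 0
  ids <- vapply(selected, function(e)
    if (length(e@id)) e@id else NA_integer_, integer(1))
  new("ConsensusResult",
      embedding = Embedding(coords(emb), method = "consensus"),
      stack = new("DistanceStack", matrices = Wk, consensus = Wtilde,
                  estimator = estimator),
      selectedIds = ids[!is.na(ids)], stress = stress)
}

#' Probability that a consensus of strong embeddings preserves a triplet
#'
#' With M independent base embeddings each preserving a triplet with
#' probability \eqn{\alpha}, the binomial aggregate
#' \eqn{\sum_{K=1}^{M} \binom{M}{K} \alpha^K (1-\alpha)^{M-K} =
#' 1 - (1-\alpha)^M} gives the probability that the triplet is preserved in
#' at least one member; monotone increasing in both arguments, so a consensus
#' built from more strong embeddings is never weaker.
#'
#' @param alpha per-embedding preservation probability in [0, 1].
#' @param M number of embeddings (>= 1).
#' @return Probability in [0, 1].
#' @examples
#' consensusSuccessProbability(0.5, 2)  # 0.75
#' @export
consensusSuccessProbability <- function(alpha, M) {
  if (any(alpha < 0 | alpha > 1)) stop("'alpha' must lie in [0, 1]")
  if (any(M < 1)) stop("'M' must be >= 1")
  1 - (1 - alpha)^M
}

#' Mean squared error between two distance matrices
#'
#' Mean over unordered object pairs of the squared entrywise difference.
#'
#' @param reference,candidate equally-shaped symmetric matrices.
#' @return Nonnegative scalar.
#' @export
pairwiseMSE <- function(reference, candidate) {
  if (!all(dim(reference) == dim(candidate))) stop("shapes differ")
  up <- upper.tri(reference)
  mean((reference[up] - candidate[up])^2)
}

#' Error bound of the mean-combined consensus (Jensen inequality check)
#'
#' Computes the average per-member error \eqn{\epsilon_{K,X}} (mean over the
#' stack of \code{pairwiseMSE} to the reference) and the error
#' \eqn{\epsilon_{\tilde X}} of the mean-combined consensus matrix, and
#' reports whether the consensus error is no larger — which convexity
#' guarantees for the mean combiner on any stack.
#'
#' @param reference the reference distance matrix.
#' @param matrices list of K candidate distance matrices.
#' @return List with \code{epsilonK} (average member error), \code{epsilonC}
#'   (consensus error) and \code{holds}.
#' @export
prop2Check <- function(reference, matrices) {
  if (!length(matrices)) stop("empty stack")
  epsK <- mean(vapply(matrices, function(W) pairwiseMSE(reference, W),
                      numeric(1)))
  Wbar <- mlCombine(matrices, "mean")
  epsC <- pairwiseMSE(reference, Wbar)
  list(epsilonK = epsK, epsilonC = epsC, holds = epsK >= epsC - 1e-12)
}
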