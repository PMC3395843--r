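# CreateEmbed: bootstrapped feature subspaces and the base-embedding ensemble.

#' Draw a bootstrapped feature-subspace plan
#'
#' M subsets of V distinct feature indices, each drawn uniformly without
#' replacement. If any of the N features is left uncovered, uncovered
#' features replace random slots of random subsets until every feature
#' appears in at least one subset. Deterministic given the seed.
#'
#' @param N total feature count.
#' @param M number of subsets; must satisfy \code{M * V >= N}.
#' @param V subset size, \code{2 <= V < N}; default
#'   \code{max(2, round(sqrt(N)))}.
#' @param seed integer seed.
#' @return A \linkS4class{SubsetPlan}.
#' @export
makeSubsetPlan <- function(N, M, V = max(2, round(sqrt(N))), seed = 1) {
  N <- as.integer(N); M <- as.integer(M); V <- as.integer(V)
  if (V < 2 || V >= N) stop("'V' must satisfy 2 <= V < N")
  if (M < ceiling(N / V)) stop("'M' too small to cover all ", N,
                               " features with subsets of ", V)
  subsets <- .withSeed(seed, {
    ss <- replicate(M, sort(sample.int(N, V)), simplify = FALSE)
    uncovered <- setdiff(seq_len(N), unlist(ss))
    while (length(uncovered)) {          # coverage repair
      f <- uncovered[1]
      m <- sample.int(M, 1)
      slot <- sample.int(V, 1)
      if (!f %in% ss[[m]]) {
        ss[[m]][slot] <- f
        ss[[m]] <- sort(ss[[m]])
      }
      uncovered <- setdiff(seq_len(N), unlist(ss))
    }
    ss
  })
  new("SubsetPlan", subsets = subsets, N = N, V = V, seed = as.integer(seed))
}

#' Generate the base-embedding ensemble (CreateEmbed)
#'
#' Applies the chosen DR method to each column-restricted view
#' \code{X[, subset_m]} of the feature matrix; all objects are retained in
#' every subspace. Embeddings are independent computations, so their results
#' do not depend on evaluation order.
#'
#' @param x \linkS4class{FeatureSet} or matrix.
#' @param plan a \linkS4class{SubsetPlan} over the N features of \code{x}.
#' @param method "pca" or "ge".
#' @param n target dimensionality, \code{n < V}.
#' @param bandwidth optional bandwidth forwarded to \code{\link{graphEmbed}}.
#' @return List of M \linkS4class{Embedding} objects (ids set to 1..M).
#' @export
createEmbeddings <- function(x, plan, method = c("pca", "ge"), n,
                             bandwidth = NULL) {
  method <- match.arg(method)
  X <- .mat(x)
  if (plan@N != ncol(X)) stop("plan covers ", plan@N, " features but data has ",
                              ncol(X))
  if (n >= plan@V) stop("'n' must be smaller than the subset size V")
  lapply(seq_along(plan@subsets), function(m) {
    sub <- plan@subsets[[m]]
    Xi <- X[, sub, drop = FALSE]
    e <- switch(method,
                pca = pcaEmbed(Xi, n),
                ge = graphEmbed(Xi, n, bandwidth = bandwidth))
    e@subset <- as.integer(sub)
    e@id <- as.integer(m)
    e
  })
}
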