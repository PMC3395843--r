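#' Principal component embedding
#'
#' Projects column-centered data onto its top-n principal axes. Deterministic
#' up to per-axis sign, which is fixed by making the largest-magnitude loading
#' of each axis positive.
#'
#' @param x a \linkS4class{FeatureSet} or numeric matrix (objects in rows).
#' @param n target dimensionality, \code{n <= min(R - 1, N)}.
#' @return An \linkS4class{Embedding} with method tag \code{"pca"}.
#' @examples
#' fs <- FeatureSet(matrix(rnorm(60), 20, 3))
#' coords(pcaEmbed(fs, 2))
#' @export
pcaEmbed <- function(x, n) {
  X <- .mat(x)
  R <- nrow(X); N <- ncol(X)
  if (n < 1 || n > min(R - 1, N))
    stop("'n' must lie in 1..min(R-1, N) = 1..", min(R - 1, N))
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = n)
  rot <- pc$rotation[, seq_len(n), drop = FALSE]
  sc <- pc$x[, seq_len(n), drop = FALSE]
  for (j in seq_len(n)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) sc[, j] <- -sc[, j]
  }
  dimnames(sc) <- NULL
  Embedding(sc, method = "pca")
}

#' Graph embedding (normalized-cut spectral embedding)
#'
#' Builds a Gaussian affinity \eqn{A(i,j) = \exp(-\|F(c_i)-F(c_j)\|_2/\sigma)}
#' (the bandwidth \eqn{\sigma} defaults to the mean pairwise distance), then
#' solves the generalized eigenproblem \eqn{(D - A)x = \lambda D x} and keeps
#' the eigenvectors of the n smallest nonzero eigenvalues as coordinates.
#'
#' @param x a \linkS4class{FeatureSet} or numeric matrix.
#' @param n target dimensionality (\code{R >= n + 2} required).
#' @param bandwidth optional kernel bandwidth \eqn{\sigma > 0}.
#' @return An \linkS4class{Embedding} with method tag \code{"ge"}.
#' @export
graphEmbed <- function(x, n, bandwidth = NULL) {
  X <- .mat(x)
  R <- nrow(X)
  if (R < n + 2) stop("graph embedding needs R >= n + 2 objects")
  d <- as.matrix(stats::dist(X))
  if (is.null(bandwidth)) {
    bandwidth <- mean(d[upper.tri(d)])
    if (!is.finite(bandwidth) || bandwidth <= 0) bandwidth <- 1
  }
  if (bandwidth <= 0) stop("'bandwidth' must be positive")
  A <- exp(-d / bandwidth)
  deg <- rowSums(A)
  offmax <- apply(A - diag(diag(A)), 1, max)
  if (any(offmax < .Machine$double.eps))
    stop("affinity graph numerically disconnected; increase 'bandwidth'")
  # symmetrized form: I - D^-1/2 A D^-1/2 shares eigenvalues with the
  # generalized problem (D - A) x = lambda D x, with x = D^-1/2 v
  s <- 1 / sqrt(deg)
  Lsym <- diag(R) - (s * A) * rep(s, each = R)
  Lsym <- (Lsym + t(Lsym)) / 2
  eig <- eigen(Lsym, symmetric = TRUE)
  lam <- rev(eig$values)                 # ascending
  vec <- eig$vectors[, rev(seq_len(R)), drop = FALSE]
  tol <- max(abs(lam)) * 1e-8
  keep <- which(lam > tol)
  if (length(keep) < n)
    stop("fewer than ", n, " nonzero Laplacian eigenvalues; reduce 'n'")
  sel <- keep[seq_len(n)]
  crd <- vec[, sel, drop = FALSE] * s
  crd <- .fixSigns(crd)
  dimnames(crd) <- NULL
  Embedding(crd, method = "ge")
}

#' Classical multidimensional scaling
#'
#' Torgerson scaling: double-centers \eqn{-\tfrac12 D^2}, takes the top-n
#' eigenpairs and scales eigenvectors by the square roots of the
#' (nonnegative-clipped) eigenvalues. If fewer than n eigenvalues are
#' positive the remaining coordinates are zero-padded with a warning.
#'
#' @param D symmetric nonnegative distance matrix with zero diagonal.
#' @param n target dimensionality.
#' @return An \linkS4class{Embedding} with method tag \code{"mds"}.
#' @examples
#' D <- as.matrix(dist(cbind(c(0, 1, 3))))
#' coords(classicalMDS(D, 1))
#' @export
classicalMDS <- function(D, n) {
  D <- as.matrix(D)
  R <- nrow(D)
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("'D' must be symmetric")
  if (any(abs(diag(D)) > 1e-12)) stop("'D' must have a zero diagonal")
  if (n < 1 || n > R) stop("'n' must lie in 1..R")
  B <- -0.5 * D^2
  rm <- rowMeans(B); gm <- mean(B)
  B <- B - outer(rm, rm, "+") + gm       # double centering
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  lam <- eig$values[seq_len(n)]
  npos <- sum(eig$values > max(abs(eig$values), .Machine$double.eps) * 1e-10)
  if (npos < n)
    warning("only ", npos, " positive eigenvalues; padding ", n - npos,
            " coordinates with zeros")
  lam[lam < 0] <- 0
  crd <- eig$vectors[, seq_len(n), drop = FALSE] *
    rep(sqrt(lam), each = R)
  crd <- .fixSigns(crd)
  dimnames(crd) <- NULL
  Embedding(crd, method = "mds")
}

#' Estimate target dimensionality from the PCA spectrum
#'
#' Returns the smallest n whose top-n principal-component eigenvalues explain
#' at least \code{threshold} of the total variance, bounded to \code{[1, N-1]}.
#'
#' @param x a \linkS4class{FeatureSet} or numeric matrix with \code{R >= 10}
#'   objects.
#' @param threshold fraction of variance to explain (default 0.95).
#' @return Integer target dimensionality.
#' @export
estimateIntrinsicDim <- function(x, threshold = 0.95) {
  X <- .mat(x)
  if (nrow(X) < 10) stop("need at least 10 objects")
  N <- ncol(X)
  ev <- stats::prcomp(X, center = TRUE, scale. = FALSE)$sdev^2
  tot <- sum(ev)
  if (tot <= .Machine$double.eps) return(1L)
  n <- which(cumsum(ev) / tot >= threshold)[1]
  if (is.na(n)) n <- length(ev)
  as.integer(max(1L, min(n, N - 1L)))
}
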