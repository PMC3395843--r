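# Synthetic study-condition generators: a two-region RGB toy image whose
# classes differ only in the red channel, a two-tissue phantom with Gaussian
# noise and a smooth multiplicative bias field, and two-class expression
# matrices with a handful of mean-shifted informative features.

.defaultRectMask <- function(height, width, fraction = 0.4) {
  side <- round(sqrt(fraction * height * width))
  r0 <- floor((height - side) / 2); c0 <- floor((width - side) / 2)
  m <- matrix(FALSE, height, width)
  m[r0 + seq_len(min(side, height - r0)), c0 + seq_len(min(side, width - c0))] <- TRUE
  m
}

#' Two-region RGB toy image with chromatic noise
#'
#' Foreground and background share their G and B means and differ only in the
#' R channel; i.i.d. Gaussian noise (sd \code{noiseSigma}, clipped to
#' [0, 255]) corrupts the G and B channels while R stays noise-free. The R
#' separation (60 gray levels) is deliberately small relative to the default
#' noise so that a 2-means split of the raw RGB values is captured by the
#' chromatic noise rather than the class structure — the scenario a consensus
#' of {R,G}/{R,B} subspace embeddings is designed to recover.
#'
#' @param height,width image size in pixels (default 100 x 100).
#' @param foregroundMask logical matrix; default centered square covering
#'   ~40\% of pixels.
#' @param fgColor,bgColor RGB triples in [0, 255]; must differ in R.
#' @param noiseSigma gray-level noise sd applied to G and B only (>= 0).
#' @param seed integer seed; identical seeds give bit-identical images.
#' @return List with \code{image} (H x W x 3 array), \code{labels} (H x W
#'   0/1 matrix, 1 = foreground) and \code{features} (a
#'   \linkS4class{FeatureSet} of per-pixel R, G, B values, pixels in
#'   column-major order, labeled).
#' @export
makeToyRGB <- function(height = 100, width = 100, foregroundMask = NULL,
                       fgColor = c(150, 120, 120), bgColor = c(90, 120, 120),
                       noiseSigma = 40, seed = 1) {
  if (height < 1 || width < 1) stop("image dimensions must be positive")
  if (noiseSigma < 0) stop("'noiseSigma' must be >= 0")
  if (fgColor[1] == bgColor[1])
    stop("foreground and background must differ in the R channel")
  if (is.null(foregroundMask)) foregroundMask <- .defaultRectMask(height, width)
  stopifnot(all(dim(foregroundMask) == c(height, width)))
  img <- array(0, c(height, width, 3))
  for (ch in 1:3)
    img[, , ch] <- ifelse(foregroundMask, fgColor[ch], bgColor[ch])
  .withSeed(seed, {
    for (ch in 2:3) {
      img[, , ch] <- img[, , ch] + stats::rnorm(height * width, 0, noiseSigma)
    }
  })
  img[, , 2:3] <- pmin(pmax(img[, , 2:3], 0), 255)
  labels <- matrix(as.integer(foregroundMask), height, width)
  feat <- cbind(R = as.vector(img[, , 1]), G = as.vector(img[, , 2]),
                B = as.vector(img[, , 3]))
  list(image = img, labels = labels,
       features = FeatureSet(feat, labels = as.vector(labels)))
}

.defaultTissueMask <- function(height, width) {
  # one tissue as an off-center disc inside the other, so both classes form
  # contiguous regions with a curved interface (texture windows see both)
  cy <- height * 0.45; cx <- width * 0.55
  r <- 0.32 * min(height, width)
  yy <- matrix(seq_len(height), height, width)
  xx <- matrix(seq_len(width), height, width, byrow = TRUE)
  matrix(as.integer((yy - cy)^2 + (xx - cx)^2 <= r^2), height, width)
}

#' Smooth multiplicative bias field
#'
#' A normalized 2-D Gaussian surface centered off-image-center, affinely
#' rescaled to mean 1 with peak-to-mean deviation (max - mean)/mean equal to
#' \code{biasPct}/100; strictly positive.
#'
#' @param height,width field size.
#' @param biasPct peak-to-mean deviation in percent.
#' @return H x W positive matrix with mean 1.
#' @export
makeBiasField <- function(height, width, biasPct) {
  if (biasPct < 0) stop("'biasPct' must be >= 0")
  if (biasPct == 0) return(matrix(1, height, width))
  cy <- height * 0.3; cx <- width * 0.7
  s <- 0.6 * min(height, width)
  yy <- matrix(seq_len(height), height, width)
  xx <- matrix(seq_len(width), height, width, byrow = TRUE)
  g <- exp(-((yy - cy)^2 + (xx - cx)^2) / (2 * s^2))
  p <- biasPct / 100
  b <- p / (max(g) - mean(g))
  field <- 1 + b * (g - mean(g))
  if (min(field) <= 0) stop("bias field not positive; lower 'biasPct'")
  field
}

#' Two-tissue phantom with noise and intensity inhomogeneity
#'
#' Each pixel takes its tissue-class mean gray level, is multiplied by a
#' smooth positive bias field with peak-to-mean deviation \code{biasPct}/100,
#' and receives additive Gaussian noise with sd equal to \code{noisePct}/100
#' of the mean (noiseless) intensity. The noise and bias grids default to the
#' levels of the emulated study, \{0, 1, 3, 5, 7, 9\}\% noise and
#' \{0, 20, 40\}\% inhomogeneity; other levels require
#' \code{allowAnyLevel = TRUE}.
#'
#' @param height,width phantom size in pixels (default 64 x 64).
#' @param tissueMask integer 0/1 matrix marking the two tissue classes;
#'   default an off-center disc of class 1 inside class 0.
#' @param classMeans gray-level means, \code{c(class0, class1)}; distinct.
#' @param noisePct,biasPct percent noise and bias levels.
#' @param allowAnyLevel allow levels outside the study grid.
#' @param seed integer seed.
#' @return List with \code{image}, \code{labels}, \code{bias},
#'   \code{noiseless} matrices.
#' @export
makePhantom <- function(height = 64, width = 64, tissueMask = NULL,
                        classMeans = c(130, 100), noisePct = 0, biasPct = 0,
                        allowAnyLevel = FALSE, seed = 1) {
  if (classMeans[1] == classMeans[2]) stop("class means must be distinct")
  if (noisePct < 0 || biasPct < 0) stop("levels must be >= 0")
  if (!allowAnyLevel) {
    if (!noisePct %in% c(0, 1, 3, 5, 7, 9))
      stop("'noisePct' outside the study grid {0,1,3,5,7,9}; ",
           "set allowAnyLevel = TRUE to override")
    if (!biasPct %in% c(0, 20, 40))
      stop("'biasPct' outside the study grid {0,20,40}; ",
           "set allowAnyLevel = TRUE to override")
  }
  if (is.null(tissueMask)) tissueMask <- .defaultTissueMask(height, width)
  stopifnot(all(dim(tissueMask) == c(height, width)))
  noiseless <- ifelse(tissueMask == 1L, classMeans[2], classMeans[1])
  bias <- makeBiasField(height, width, biasPct)
  sigma <- noisePct / 100 * mean(noiseless)
  img <- noiseless * bias
  if (sigma > 0)
    img <- img + .withSeed(seed, matrix(stats::rnorm(height * width, 0, sigma),
                                        height, width))
  list(image = img, labels = tissueMask, bias = bias, noiseless = noiseless)
}

#' Two-class expression-like matrix with mean-shifted informative features
#'
#' Gaussian features with unit variance; informative features differ between
#' the classes only by a standardized mean shift of \code{effectSize}, noise
#' features are class-independent. Column order is randomized (seeded); the
#' post-shuffle indices of the informative features are returned.
#'
#' @param nPerClass samples per class (> 0).
#' @param nInformative,nNoise feature counts (informative > 0, noise >= 0).
#' @param effectSize standardized mean shift (>= 0).
#' @param seed integer seed.
#' @return List with \code{features} (a labeled \linkS4class{FeatureSet},
#'   class-0 samples first) and \code{informative} (column indices).
#' @export
makeExpression <- function(nPerClass = 50, nInformative = 10, nNoise = 90,
                           effectSize = 1, seed = 1) {
  if (nPerClass < 1 || nInformative < 1 || nNoise < 0)
    stop("counts must be positive (noise features may be 0)")
  if (effectSize < 0) stop("'effectSize' must be >= 0")
  R <- 2L * as.integer(nPerClass)
  N <- as.integer(nInformative + nNoise)
  labels <- rep(c(0L, 1L), each = nPerClass)
  .withSeed(seed, {
    X <- matrix(stats::rnorm(R * N), R, N)
    X[labels == 1L, seq_len(nInformative)] <-
      X[labels == 1L, seq_len(nInformative)] + effectSize
    ord <- sample.int(N)
  })
  X <- X[, ord, drop = FALSE]
  informative <- match(seq_len(nInformative), ord)
  colnames(X) <- paste0("g", seq_len(N))
  list(features = FeatureSet(X, labels = labels),
       informative = sort(informative))
}
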