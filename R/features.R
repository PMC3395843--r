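# Per-pixel texture features: windowed GLCM Haralick statistics and
# first-order window statistics, plus t-statistic feature pruning for
# expression matrices.

.haralickNames <- c("energy", "contrast", "correlation", "variance",
                    "inverseDifferenceMoment", "sumAverage", "sumVariance",
                    "sumEntropy", "entropy", "differenceVariance",
                    "differenceEntropy", "infoCorrelation1",
                    "infoCorrelation2", "maximalCorrelationCoefficient")

.defaultOffsets <- function()
  matrix(c(0L, 1L,  1L, 0L,  1L, 1L,  1L, -1L), ncol = 2, byrow = TRUE)

#' Quantize a grayscale image to integer gray levels
#'
#' Linear binning of the intensity range into \code{grayLevels} levels
#' (0-based). Pass fixed \code{range} bin edges to make the quantization —
#' and hence the Haralick features — invariant to adding a constant.
#'
#' @param image numeric matrix.
#' @param grayLevels number of levels (>= 2).
#' @param range optional \code{c(lo, hi)}; defaults to the image range.
#' @return Integer matrix with values in 0..grayLevels-1.
#' @export
quantizeImage <- function(image, grayLevels = 64, range = NULL) {
  if (grayLevels < 2) stop("'grayLevels' must be >= 2")
  if (is.null(range)) range <- base::range(image)
  lo <- range[1]; hi <- range[2]
  if (hi <= lo) {
    q <- matrix(0L, nrow(image), ncol(image))
  } else {
    q <- floor((image - lo) / (hi - lo) * grayLevels)
    q[q < 0] <- 0
    q[q > grayLevels - 1] <- grayLevels - 1
    storage.mode(q) <- "integer"
  }
  q
}

#' Per-pixel Haralick texture features
#'
#' For every pixel, a symmetric normalized gray-level co-occurrence matrix is
#' accumulated inside the surrounding window (reflect padding at borders;
#' both pixels of a co-occurring pair must fall inside the window), one GLCM
#' per displacement offset, and the 14 Haralick statistics — energy,
#' contrast, correlation, variance, inverse difference moment, sum average,
#' sum variance, sum entropy, entropy, difference variance, difference
#' entropy, the two information measures of correlation, and the maximal
#' correlation coefficient — are averaged over the offsets. Gray tones are
#' 1-based level values; the sum-variance statistic is centered on the sum
#' average. Statistics that are undefined on a degenerate (constant) window
#' — correlation and the information measures — are defined as 0.
#'
#' @param image numeric matrix (single-channel).
#' @param window odd window width >= 3 (default 5).
#' @param grayLevels quantization levels (default 64).
#' @param offsets integer matrix of (dy, dx) displacements; default
#'   \{(0,1), (1,0), (1,1), (1,-1)\}.
#' @param range optional fixed quantization range, see
#'   \code{\link{quantizeImage}}.
#' @param labels optional 0/1 label matrix matching the image.
#' @return A \linkS4class{FeatureSet} with one row per pixel (column-major
#'   order) and 14 columns.
#' @export
haralickPerPixel <- function(image, window = 5, grayLevels = 64,
                             offsets = .defaultOffsets(), range = NULL,
                             labels = NULL) {
  if (window < 3 || window %% 2 == 0) stop("'window' must be odd and >= 3")
  if (window > min(dim(image))) stop("'window' larger than the image")
  q <- quantizeImage(image, grayLevels, range)
  offsets <- matrix(as.integer(offsets), ncol = 2)
  f <- .haralickCpp(q, as.integer(window), offsets, as.integer(grayLevels))
  colnames(f) <- .haralickNames
  FeatureSet(f, labels = if (is.null(labels)) integer(0) else as.vector(labels))
}

#' Per-pixel first-order window statistics
#'
#' Mean, median, standard deviation and range of the intensities inside the
#' window around each pixel (reflect padding).
#'
#' @inheritParams haralickPerPixel
#' @return A \linkS4class{FeatureSet} with columns mean, median, sd, range.
#' @export
firstOrderPerPixel <- function(image, window = 5, labels = NULL) {
  if (window %% 2 == 0) stop("'window' must be odd")
  if (window > min(dim(image))) stop("'window' larger than the image")
  f <- .firstOrderCpp(matrix(as.double(image), nrow(image)), as.integer(window))
  colnames(f) <- c("mean", "median", "sd", "range")
  FeatureSet(f, labels = if (is.null(labels)) integer(0) else as.vector(labels))
}

#' Welch t-statistics for every feature of a labeled FeatureSet
#'
#' @param x labeled \linkS4class{FeatureSet} (both classes with >= 2 samples).
#' @return Numeric vector of Welch t statistics (class 1 minus class 0); a
#'   zero-variance, nonzero-difference feature yields +/-Inf.
#' @export
welchT <- function(x) {
  X <- .mat(x); l <- .labels(x)
  if (!length(l)) stop("labels required")
  if (min(table(l)) < 2) stop("each class needs >= 2 samples")
  i1 <- l == 1L; i0 <- !i1
  n1 <- sum(i1); n0 <- sum(i0)
  m1 <- colMeans(X[i1, , drop = FALSE]); m0 <- colMeans(X[i0, , drop = FALSE])
  v1 <- apply(X[i1, , drop = FALSE], 2, stats::var)
  v0 <- apply(X[i0, , drop = FALSE], 2, stats::var)
  se <- sqrt(v1 / n1 + v0 / n0)
  t <- (m1 - m0) / se
  t[se == 0 & m1 == m0] <- 0
  t[se == 0 & m1 != m0] <- Inf * sign(m1 - m0)[se == 0 & m1 != m0]
  t
}

#' Prune a labeled feature matrix to its k most class-informative features
#'
#' Features are ranked by the absolute two-sample Welch t statistic; the top
#' k are retained in their original column order. A zero-variance feature
#' with distinct class means separates the classes perfectly and ranks first
#' (|t| = Inf).
#'
#' @param x labeled \linkS4class{FeatureSet}.
#' @param k number of features to keep (<= N).
#' @return List with \code{features} (pruned \linkS4class{FeatureSet}),
#'   \code{kept} (retained column indices, ascending) and \code{ranking}
#'   (all columns ordered by decreasing |t|).
#' @export
tStatPrune <- function(x, k) {
  X <- .mat(x)
  if (k > ncol(X)) stop("'k' exceeds the feature count")
  t <- welchT(x)
  ranking <- order(abs(t), decreasing = TRUE)
  kept <- sort(ranking[seq_len(k)])
  list(features = FeatureSet(X[, kept, drop = FALSE], labels = .labels(x)),
       kept = kept, ranking = ranking)
}

#' Read a grayscale image from PNG, TIFF or NIfTI
#'
#' Multi-channel images are averaged to one channel; for 3-D NIfTI volumes a
#' single axial slice is extracted. Intensities are returned on the scale
#' stored in the file (PNG/TIFF readers return [0, 1]).
#'
#' @param path image file; format inferred from the extension.
#' @param slice slice index for 3-D NIfTI input (default: middle slice).
#' @return Numeric matrix (height x width).
#' @export
readGrayImage <- function(path, slice = NULL) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("package 'tiff' required to read TIFF")
      tiff::readTIFF(path)
    },
    nii = {
      if (!requireNamespace("RNifti", quietly = TRUE))
        stop("package 'RNifti' required to read NIfTI")
      as.array(RNifti::readNifti(path))
    },
    stop("unsupported image format '.", ext, "'"))
  if (length(dim(img)) == 3) {
    if (ext == "nii") {
      if (is.null(slice)) slice <- ceiling(dim(img)[3] / 2)
      img <- img[, , slice]
    } else {
      img <- apply(img[, , seq_len(min(3, dim(img)[3])), drop = FALSE],
                   c(1, 2), mean)                     # channels -> gray
    }
  }
  matrix(as.double(img), nrow(img), ncol(img))
}
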