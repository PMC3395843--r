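# End-to-end pipelines: run configuration, the phantom noise x bias sweep,
# the estimator-robustness comparison, and plain-text writers.

#' Build a consensus-embedding run configuration
#'
#' All tunable parameters of the pipeline in one serializable list; every
#' run writes its resolved configuration beside its outputs.
#'
#' @param drMethod base DR method, "ge" or "pca".
#' @param n target dimensionality of every embedding.
#' @param M number of base embeddings.
#' @param V feature-subset size; NULL for \code{max(2, round(sqrt(N)))}.
#' @param thetaFactor,thetaMode strong-embedding threshold, see
#'   \code{\link{selEmbed}}. The pipeline default keeps embeddings within
#'   \code{thetaFactor} of the best scorer ("within-of-max"), the reading
#'   under which selection actually excludes weak members; the literal
#'   "factor-of-max" rule is available too.
#' @param estimator ML estimator fusing the distance stack, "median"/"mean".
#' @param strengthMode "supervised" (cluster-overlap accuracy; needs labels)
#'   or "rsi" (R-squared index).
#' @param clusterer evaluation clusterer, "kmeans" or "hclust".
#' @param clusterK clusters used when scoring embeddings (default 2).
#' @param bandwidth mean-shift bandwidth (z-scored units); NULL = Silverman.
#' @param geBandwidth affinity bandwidth for graph embedding; NULL = mean
#'   pairwise distance.
#' @param maxReps cap on mean-shift representatives before bandwidth
#'   escalation.
#' @param window,grayLevels Haralick extraction parameters for image inputs.
#' @param standardize z-score feature columns before subspace embedding
#'   (recommended: texture features differ by orders of magnitude in scale).
#' @param seed master seed for all randomness in the run.
#' @return Named list of class \code{ceConfig}.
#' @export
consensusConfig <- function(drMethod = c("ge", "pca"), n = 3, M = 40,
                            V = NULL, thetaFactor = 0.15,
                            thetaMode = c("within-of-max", "factor-of-max"),
                            estimator = c("median", "mean"),
                            strengthMode = c("supervised", "rsi"),
                            clusterer = c("kmeans", "hclust"), clusterK = 2,
                            bandwidth = NULL, geBandwidth = NULL,
                            maxReps = 400, window = 5, grayLevels = 64,
                            standardize = TRUE, seed = 1) {
  cfg <- list(drMethod = match.arg(drMethod), n = as.integer(n),
              M = as.integer(M), V = if (is.null(V)) NULL else as.integer(V),
              thetaFactor = thetaFactor, thetaMode = match.arg(thetaMode),
              estimator = match.arg(estimator),
              strengthMode = match.arg(strengthMode),
              clusterer = match.arg(clusterer),
              clusterK = as.integer(clusterK), bandwidth = bandwidth,
              geBandwidth = geBandwidth, maxReps = as.integer(maxReps),
              window = as.integer(window),
              grayLevels = as.integer(grayLevels),
              standardize = isTRUE(standardize), seed = as.integer(seed))
  class(cfg) <- c("ceConfig", "list")
  cfg
}

#' @rdname consensusConfig
#' @param config a \code{ceConfig} list.
#' @param path file path for the JSON serialization.
#' @export
saveConfig <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname consensusConfig
#' @export
loadConfig <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(consensusConfig, raw)
}

.resolveClusterer <- function(name, seed) {
  switch(name,
         kmeans = function(x, k) replicatedKMeans(x, k, seed = seed),
         hclust = function(x, k) hierarchicalCluster(x, k),
         stop("unknown clusterer '", name, "'"))
}

#' Run the full consensus pipeline on one input and write its outputs
#'
#' Accepts a grayscale-image list (as returned by \code{\link{makePhantom}}),
#' an RGB-image list (\code{\link{makeToyRGB}}) or a bare
#' \linkS4class{FeatureSet}. Image inputs are turned into per-pixel features
#' (Haralick for grayscale, raw channels for RGB) and routed through
#' mean-shift sub-sampling; small tabular inputs are embedded directly. The
#' final coordinates are clustered and, when ground truth is present, scored.
#'
#' Outputs written to \code{outputDir}: \code{embedding.tsv},
#' \code{metrics.tsv}, \code{config.json}, \code{provenance.json}, and (for
#' image inputs) \code{labelmap.png}. Two runs with identical configuration
#' and input produce byte-identical files.
#'
#' @param input see above.
#' @param config a \code{\link{consensusConfig}}.
#' @param outputDir directory (created if missing).
#' @param subsample logical; NULL = subsample iff more than 1000 objects.
#' @return Invisibly, a list with coords, partition, metrics.
#' @export
runPipeline <- function(input, config = consensusConfig(), outputDir,
                        subsample = NULL) {
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  shape <- NULL
  if (is(input, "FeatureSet")) {
    fs <- input
  } else if (is.list(input) && !is.null(input$image)) {
    if (length(dim(input$image)) == 3) {
      fs <- input$features
      shape <- dim(input$image)[1:2]
    } else {
      shape <- dim(input$image)
      fs <- haralickPerPixel(input$image, window = config$window,
                             grayLevels = config$grayLevels,
                             labels = input$labels)
    }
  } else stop("unsupported input; pass a FeatureSet or an image list")
  labels <- .labels(fs)
  if (config$strengthMode == "supervised" && !length(labels))
    stop("no labels in input but strengthMode = 'supervised'; ",
         "use strengthMode = 'rsi'")
  R <- nrow(.mat(fs))
  if (is.null(subsample)) subsample <- R > 1000
  if (subsample) {
    res <- consEmbedMS(fs, config)
    crd <- res$coords
  } else {
    res <- consensusEmbed(fs, config)
    crd <- coords(res$consensus)
  }
  part <- replicatedKMeans(crd, config$clusterK, seed = config$seed)
  metrics <- data.frame(
    metric = c("stress", "psiMax", "psiMedian", "theta", "selected",
               "rsi"),
    value = c(res$consensus@stress, max(res$psi), stats::median(res$psi),
              res$theta, length(res$selected),
              rsIndex(crd, clusterLabels(part))))
  if (length(labels)) {
    part@accuracy <- clusterAccuracy(clusterLabels(part), labels)
    metrics <- rbind(metrics,
                     data.frame(metric = "accuracy", value = part@accuracy))
  }
  writeEmbeddingTSV(crd, file.path(outputDir, "embedding.tsv"))
  utils::write.table(format(metrics, digits = 15),
                     file.path(outputDir, "metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  saveConfig(config, file.path(outputDir, "config.json"))
  jsonlite::write_json(
    list(selected = res$selected, theta = res$theta, psi = res$psi,
         representatives = if (!is.null(res$map)) nrow(res$map@repCoords)
                           else R),
    file.path(outputDir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(shape)) {
    lm <- renderLabelMap(part, shape)
    png::writePNG(aperm(lm$image, c(1, 2, 3)),
                  file.path(outputDir, "labelmap.png"))
  }
  invisible(list(coords = crd, partition = part, metrics = metrics,
                 result = res))
}

#' Write / read embedding coordinates as TSV
#'
#' @param coords numeric matrix of embedding coordinates.
#' @param path file path.
#' @export
writeEmbeddingTSV <- function(coords, path) {
  df <- data.frame(object = seq_len(nrow(coords)), coords)
  colnames(df) <- c("object", paste0("dim", seq_len(ncol(coords))))
  utils::write.table(format(df, digits = 15), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeEmbeddingTSV
#' @export
readEmbeddingTSV <- function(path) {
  df <- utils::read.delim(path)
  as.matrix(df[, -1, drop = FALSE])
}

#' Write a FeatureSet as TSV (features in columns, optional label column)
#'
#' @param x a \linkS4class{FeatureSet}.
#' @param path file path.
#' @export
writeFeatureTSV <- function(x, path) {
  df <- as.data.frame(.mat(x))
  l <- .labels(x)
  if (length(l)) df$label <- l
  utils::write.table(format(df, digits = 15), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTSV
#' @export
readFeatureTSV <- function(path) {
  df <- utils::read.delim(path)
  if ("label" %in% colnames(df)) {
    FeatureSet(as.matrix(df[setdiff(colnames(df), "label")]),
               labels = df$label)
  } else FeatureSet(as.matrix(df))
}

# one phantom image through every comparator of the noise x bias study
.phantomRun <- function(noisePct, biasPct, seed, config) {
  ph <- makePhantom(noisePct = noisePct, biasPct = biasPct, seed = seed)
  pixLabels <- as.vector(ph$labels)
  fs <- haralickPerPixel(ph$image, window = config$window,
                         grayLevels = config$grayLevels, labels = ph$labels)
  rawPart <- replicatedKMeans(fs, 2, seed = config$seed)
  accRaw <- clusterAccuracy(clusterLabels(rawPart), pixLabels)

  map <- meanShiftReduce(fs, bandwidth = config$bandwidth)
  while (nrow(map@repCoords) > config$maxReps)
    map <- meanShiftReduce(fs, bandwidth = map@bandwidth * 1.3)
  nrep <- nrow(map@repCoords)
  repLabels <- vapply(seq_len(nrep), function(m)
    as.integer(mean(pixLabels[map@assignment == m]) >= 0.5), integer(1))
  repFS <- FeatureSet(map@repCoords, labels = repLabels)

  mapAcc <- function(emb) {
    part <- replicatedKMeans(emb, 2, seed = config$seed)
    clusterAccuracy(clusterLabels(part)[map@assignment], pixLabels)
  }
  repZ <- if (isTRUE(config$standardize)) scale(map@repCoords) else
    map@repCoords
  accGE <- mapAcc(graphEmbed(repZ, config$n, bandwidth = config$geBandwidth))
  accMDS <- mapAcc(classicalMDS(pairwiseDistances(repFS), config$n))
  wts <- tabulate(map@assignment, nbins = nrep)
  cons <- consensusEmbed(repFS, config, weights = wts)
  accCons <- mapAcc(coords(cons$consensus))
  data.frame(noise = noisePct, bias = biasPct, seed = seed,
             method = c("raw", "mds", "ge", "consensus"),
             accuracy = c(accRaw, accMDS, accGE, accCons))
}

#' Phantom tissue-partition sweep over the noise x bias grid
#'
#' Generates \code{imagesPerCell} phantom images for every combination of
#' noise and inhomogeneity level, extracts per-pixel Haralick features and
#' scores the four comparators — k-means on the raw feature space, classical
#' MDS of raw-feature distances, a single graph embedding, and the consensus
#' graph embedding (the latter three computed on mean-shift representatives
#' and mapped back to pixel level).
#'
#' @param noiseLevels,biasLevels percent levels (defaults: the full study
#'   grid \{0,1,3,5,7,9\} x \{0,20,40\}).
#' @param imagesPerCell independent phantoms per cell (default 3).
#' @param config a \code{\link{consensusConfig}}.
#' @param seed master seed for the phantom noise draws.
#' @return Long data.frame: noise, bias, seed, method, accuracy.
#' @export
sweepNoiseBias <- function(noiseLevels = c(0, 1, 3, 5, 7, 9),
                           biasLevels = c(0, 20, 40), imagesPerCell = 3,
                           config = consensusConfig(), seed = 1) {
  if (!length(noiseLevels) || !length(biasLevels)) stop("empty grid")
  cells <- expand.grid(noise = noiseLevels, bias = biasLevels)
  seeds <- .childSeeds(seed, imagesPerCell)
  out <- list()
  for (i in seq_len(nrow(cells)))
    for (j in seq_len(imagesPerCell))
      out[[length(out) + 1]] <-
        .phantomRun(cells$noise[i], cells$bias[i], seeds[j], config)
  do.call(rbind, out)
}

#' Summarize a sweep into a per-cell mean/sd accuracy table
#'
#' @param sweep long data.frame from \code{\link{sweepNoiseBias}}.
#' @return Wide data.frame, one row per noise x bias cell, columns
#'   \code{<method>_mean} and \code{<method>_sd}.
#' @export
summarizeSweep <- function(sweep) {
  agg <- stats::aggregate(accuracy ~ noise + bias + method, sweep,
                          function(a) c(mean = mean(a), sd = stats::sd(a)))
  wide <- stats::reshape(
    data.frame(noise = agg$noise, bias = agg$bias, method = agg$method,
               mean = agg$accuracy[, "mean"], sd = agg$accuracy[, "sd"]),
    idvar = c("noise", "bias"), timevar = "method", direction = "wide")
  wide[order(wide$noise, wide$bias), ]
}

#' Median vs mean fusion under a possible adversarial member
#'
#' Generates and selects the base-embedding ensemble once, then fuses the
#' selected embeddings with both the median and the mean estimator. With
#' \code{adversarial = TRUE}, one corrupted embedding (a selected member
#' with its rows permuted, seeded) is appended to the selected set before
#' fusion, so the two estimators face the same outlier.
#'
#' @param x labeled \linkS4class{FeatureSet}.
#' @param config a \code{\link{consensusConfig}}.
#' @param adversarial inject one corrupted member.
#' @param seed seed for the adversarial permutation.
#' @param weights optional object weights (e.g. pixel counts of mean-shift
#'   representatives) used both for embedding selection and for the reported
#'   accuracies.
#' @return Named numeric: cluster-overlap accuracy of the median- and
#'   mean-fused consensus embeddings.
#' @export
estimatorComparison <- function(x, config = consensusConfig(),
                                adversarial = FALSE, seed = 1,
                                weights = NULL) {
  labels <- .labels(x)
  if (!length(labels)) stop("labels required")
  sel <- .ensembleSelect(x, config, weights = weights)$sel
  members <- sel$embeddings
  if (adversarial) {
    bad <- members[[1]]
    perm <- .withSeed(seed, sample.int(nrow(bad@coords)))
    bad@coords <- bad@coords[perm, , drop = FALSE]
    members <- c(members, bad)
  }
  vapply(c("median", "mean"), function(est) {
    cons <- calcConsEmbed(members, n = config$n, estimator = est)
    part <- replicatedKMeans(coords(cons), config$clusterK,
                             seed = config$seed)
    clusterAccuracy(clusterLabels(part), labels, weights = weights)
  }, numeric(1))
}

#' Toy-image comparison: consensus vs raw-color k-means vs single embedding
#'
#' Runs the two-region RGB toy image (classes separable only in R, chromatic
#' noise on G and B) through three pixel classifiers: k-means on the raw RGB
#' values, k-means on a single graph embedding of the full RGB space, and
#' k-means on the consensus graph embedding built from bootstrapped
#' two-channel subspaces \{R,G\}, \{R,B\}, \{G,B\}. All three operate at
#' pixel level on raw (commensurate) channel values; the image is kept at
#' 30 x 30 pixels so that every base embedding is a dense eigenproblem.
#' With the default noise level the chromatic noise dominates both the raw
#' clustering and the full-space affinity, while the R-bearing subspaces
#' remain individually recoverable — the configuration the consensus is
#' designed for.
#'
#' @param seed seed for the toy image noise draw.
#' @param config a \code{\link{consensusConfig}}; defaults to the toy
#'   settings (graph embedding, n = 1, V = 2, M = 12, no standardization).
#' @param height,width toy image size (default 30 x 30).
#' @return Named numeric: pixel accuracy of \code{raw}, \code{ge} and
#'   \code{consensus}.
#' @export
toyComparison <- function(seed,
                          config = consensusConfig(drMethod = "ge", n = 1,
                                                   V = 2, M = 12,
                                                   standardize = FALSE,
                                                   seed = 1),
                          height = 30, width = 30) {
  toy <- makeToyRGB(height = height, width = width, seed = seed)
  fs <- toy$features
  lab <- .labels(fs)
  acc <- function(emb) {
    p <- replicatedKMeans(emb, 2, seed = config$seed)
    clusterAccuracy(clusterLabels(p), lab)
  }
  accRaw <- acc(fs)
  accGE <- acc(graphEmbed(featureValues(fs), 2,
                          bandwidth = config$geBandwidth))
  cons <- consensusEmbed(fs, config)
  accCons <- acc(coords(cons$consensus))
  c(raw = accRaw, ge = accGE, consensus = accCons)
}
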