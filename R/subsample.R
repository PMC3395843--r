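# Mean-shift object sub-sampling (ConsEmbedMS): replace R objects by their
# density modes, run the consensus pipeline on the representatives, and map
# the result back to full resolution.

#' Mean-shift reduction of objects to representative modes
#'
#' Features are z-scored per column (so the bandwidth is scale-free), then
#' every object's trajectory follows Gaussian-kernel mean shift over the
#' fixed data until the shift falls below \code{tol * bandwidth} or
#' \code{maxIter} iterations. Converged trajectory positions within
#' \code{bandwidth / 2} of each other are merged into one mode; every object
#' is assigned to the mode its trajectory reaches. The reduction factor t is
#' determined by the number of stable modes, not set in advance.
#'
#' Identical trajectories are pooled between iterations (they can never
#' separate again under mean shift over fixed data), which shrinks the
#' active set quickly without changing the fixed points.
#'
#' @param x \linkS4class{FeatureSet} or matrix.
#' @param bandwidth kernel bandwidth in z-scored units; default a
#'   Silverman-style rule \eqn{(4 / ((d + 2) R))^{1/(d+4)}}.
#' @param tol relative convergence tolerance (default 1e-4).
#' @param maxIter iteration cap (default 300).
#' @return A \linkS4class{SubsampleMap}; representative coordinates are
#'   returned in the original feature units.
#' @export
meanShiftReduce <- function(x, bandwidth = NULL, tol = 1e-4, maxIter = 300) {
  X <- .mat(x)
  R <- nrow(X); d <- ncol(X)
  if (R < 1) stop("no objects")
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  Z <- scale(X, center = ctr, scale = scl)
  if (is.null(bandwidth)) bandwidth <- (4 / ((d + 2) * R))^(1 / (d + 4))
  if (bandwidth <= 0) stop("'bandwidth' must be positive")
  h <- bandwidth

  # active unique trajectories + membership of each object (trajectories
  # that coincide can never separate again, so they are pooled as they merge)
  Y <- unique(Z)
  group <- match(do.call(paste, c(as.data.frame(Z), sep = "\r")),
                 do.call(paste, c(as.data.frame(Y), sep = "\r")))
  done <- rep(FALSE, nrow(Y))
  for (it in seq_len(maxIter)) {
    act <- which(!done)
    if (!length(act)) break
    Ynew <- .msStepCpp(Y[act, , drop = FALSE], Z, h)
    shift <- sqrt(rowSums((Ynew - Y[act, , drop = FALSE])^2))
    Y[act, ] <- Ynew
    done[act[shift < tol * h]] <- TRUE
    # pool trajectories that have collapsed onto each other
    key <- do.call(paste, c(as.data.frame(round(Y / (h * 0.02))), sep = "\r"))
    first <- !duplicated(key)
    if (!all(first)) {
      newIdx <- match(key, key[first])   # new representative index per row
      done <- vapply(split(done, newIdx), any, logical(1))
      Y <- Y[first, , drop = FALSE]
      group <- newIdx[group]
    }
  }
  # merge modes within bandwidth / 2 (greedy, heaviest first)
  wt <- tabulate(group, nbins = nrow(Y))
  ord <- order(wt, decreasing = TRUE)
  modeOf <- integer(nrow(Y))
  centers <- list()
  for (i in ord) {
    placed <- FALSE
    for (m in seq_along(centers)) {
      if (sqrt(sum((Y[i, ] - centers[[m]])^2)) < h / 2) {
        modeOf[i] <- m; placed <- TRUE; break
      }
    }
    if (!placed) {
      centers[[length(centers) + 1]] <- Y[i, ]
      modeOf[i] <- length(centers)
    }
  }
  assignment <- modeOf[group]
  reps <- do.call(rbind, centers)
  reps <- sweep(sweep(reps, 2, scl, "*"), 2, ctr, "+")  # back to data units
  colnames(reps) <- colnames(X)
  new("SubsampleMap", repCoords = reps, assignment = as.integer(assignment),
      bandwidth = h)
}

#' Consensus embedding with mean-shift sub-sampling (ConsEmbedMS)
#'
#' Reduces the objects to mean-shift representatives, runs the full
#' generate / select / combine consensus pipeline on the representatives,
#' and maps every original object back to its representative's consensus
#' coordinates. Representative labels (when labels are present) are the
#' majority label of the assigned objects.
#'
#' If the mode count exceeds \code{maxReps} the bandwidth is escalated by
#' factors of 1.3 until the representative set is small enough; the final
#' bandwidth is recorded in the returned map.
#'
#' @param x \linkS4class{FeatureSet} (labels optional).
#' @param config a \code{\link{consensusConfig}} list.
#' @return List with \code{coords} (full-resolution consensus coordinates),
#'   \code{consensus} (\linkS4class{ConsensusResult} on the
#'   representatives), \code{map} (\linkS4class{SubsampleMap}),
#'   \code{repLabels}, \code{plan}, \code{psi} and \code{theta}.
#' @export
consEmbedMS <- function(x, config = consensusConfig()) {
  X <- .mat(x); labels <- .labels(x)
  cfg <- config
  map <- meanShiftReduce(X, bandwidth = cfg$bandwidth)
  while (nrow(map@repCoords) > cfg$maxReps) {
    map <- meanShiftReduce(X, bandwidth = map@bandwidth * 1.3)
  }
  nrep <- nrow(map@repCoords)
  if (nrep < cfg$n + 2)
    stop("only ", nrep, " representatives; decrease 'bandwidth'")
  repLabels <- integer(0)
  if (length(labels)) {
    repLabels <- vapply(seq_len(nrep), function(m) {
      as.integer(mean(labels[map@assignment == m]) >= 0.5)
    }, integer(1))
  }
  fs <- FeatureSet(map@repCoords,
                   labels = if (length(unique(repLabels)) == 2) repLabels
                            else integer(0))
  wts <- tabulate(map@assignment, nbins = nrep)
  res <- consensusEmbed(fs, cfg, weights = wts)
  coordsFull <- coords(res$consensus)[map@assignment, , drop = FALSE]
  c(res, list(coords = coordsFull, map = map, repLabels = repLabels))
}

#' Consensus embedding of a feature set (no sub-sampling)
#'
#' CreateEmbed / SelEmbed / CalcConsEmbed in sequence: draws the subset plan,
#' generates the base embeddings, scores them (supervised cluster-overlap
#' accuracy when labels are present and \code{strengthMode = "supervised"},
#' otherwise the R-squared index), selects the strong ones and fuses their
#' normalized distance matrices into the consensus embedding.
#'
#' @param x \linkS4class{FeatureSet}.
#' @param config a \code{\link{consensusConfig}} list.
#' @param weights optional object weights used when scoring embeddings (see
#'   \code{\link{clusterAccuracy}}).
#' @return List with \code{consensus} (\linkS4class{ConsensusResult}),
#'   \code{plan}, \code{psi}, \code{theta}, \code{selected} (indices).
#' @export
consensusEmbed <- function(x, config = consensusConfig(), weights = NULL) {
  cfg <- config
  es <- .ensembleSelect(x, cfg, weights = weights)
  cons <- calcConsEmbed(es$sel$embeddings, n = cfg$n,
                        estimator = cfg$estimator)
  list(consensus = cons, plan = es$plan, psi = es$sel$psi,
       theta = es$sel$theta, selected = es$sel$Q)
}

# CreateEmbed + strength scoring + SelEmbed, shared by the pipelines
.ensembleSelect <- function(x, cfg, weights = NULL) {
  X <- .mat(x); labels <- .labels(x)
  if (isTRUE(cfg$standardize)) {
    sds <- apply(X, 2, stats::sd)
    sds[sds == 0 | !is.finite(sds)] <- 1
    X <- scale(X, center = TRUE, scale = sds)
    x <- FeatureSet(X, labels = labels)
  }
  N <- ncol(X)
  V <- if (is.null(cfg$V)) max(2, round(sqrt(N))) else cfg$V
  V <- max(V, cfg$n + 1)
  plan <- makeSubsetPlan(N, cfg$M, V, seed = cfg$seed)
  embs <- createEmbeddings(x, plan, method = cfg$drMethod, n = cfg$n,
                           bandwidth = cfg$geBandwidth)
  supervised <- cfg$strengthMode == "supervised"
  if (supervised && !length(labels))
    stop("strengthMode 'supervised' needs labels; use strengthMode = 'rsi'")
  clusterer <- .resolveClusterer(cfg$clusterer, cfg$seed)
  strengths <- vapply(embs, function(e) {
    if (supervised)
      supervisedStrength(e, labels, k = cfg$clusterK, clusterer = clusterer,
                         weights = weights)
    else
      unsupervisedStrength(e, k = cfg$clusterK, clusterer = clusterer)
  }, numeric(1))
  sel <- selEmbed(embs, strengths = strengths, thetaMode = cfg$thetaMode,
                  thetaFactor = cfg$thetaFactor)
  list(plan = plan, embeddings = embs, sel = sel)
}
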