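#' @describeIn FeatureSet-class the object x feature matrix
#' @param x object
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))
setMethod("featureValues", "FeatureSet", function(x) x@values)

#' @describeIn FeatureSet-class the binary labels (length 0 when unlabeled)
#' @export
setGeneric("objectLabels", function(x) standardGeneric("objectLabels"))
setMethod("objectLabels", "FeatureSet", function(x) x@labels)

#' @describeIn Embedding-class embedding coordinates (R x n matrix)
#' @param x object
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))
setMethod("coords", "Embedding", function(x) x@coords)
setMethod("coords", "ConsensusResult", function(x) x@embedding@coords)

#' @describeIn Embedding-class the DR method tag
#' @export
setGeneric("drMethod", function(x) standardGeneric("drMethod"))
setMethod("drMethod", "Embedding", function(x) x@method)

#' @describeIn Embedding-class the source feature subset (may be empty)
#' @export
setGeneric("featureSubset", function(x) standardGeneric("featureSubset"))
setMethod("featureSubset", "Embedding", function(x) x@subset)

#' @describeIn Embedding-class the embedding strength, NA until scored
#' @export
setGeneric("strength", function(x) standardGeneric("strength"))
setMethod("strength", "Embedding", function(x)
  if (length(x@strength)) x@strength else NA_real_)
setMethod("strength", "TripletStats", function(x) x@psi)

#' @describeIn SubsetPlan-class the list of feature subsets
#' @param x object
#' @export
setGeneric("subsets", function(x) standardGeneric("subsets"))
setMethod("subsets", "SubsetPlan", function(x) x@subsets)

#' @describeIn DistanceStack-class the consensus distance matrix
#' @param x object
#' @export
setGeneric("consensusMatrix", function(x) standardGeneric("consensusMatrix"))
setMethod("consensusMatrix", "DistanceStack", function(x) x@consensus)
setMethod("consensusMatrix", "ConsensusResult", function(x) x@stack@consensus)

#' @describeIn DistanceStack-class the list of normalized member matrices
#' @export
setGeneric("stackMatrices", function(x) standardGeneric("stackMatrices"))
setMethod("stackMatrices", "DistanceStack", function(x) x@matrices)

#' @describeIn SubsampleMap-class representative feature vectors
#' @param x object
#' @export
setGeneric("representatives", function(x) standardGeneric("representatives"))
setMethod("representatives", "SubsampleMap", function(x) x@repCoords)

#' @describeIn SubsampleMap-class object -> representative index map
#' @export
setGeneric("assignment", function(x) standardGeneric("assignment"))
setMethod("assignment", "SubsampleMap", function(x) x@assignment)

#' @describeIn Partition-class cluster ids, one per object
#' @param x object
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
setMethod("clusterLabels", "Partition", function(x) x@labels)

setMethod("show", "FeatureSet", function(object) {
  cat("FeatureSet:", nrow(object@values), "objects x",
      ncol(object@values), "features;",
      if (length(object@labels)) sprintf("labeled (%d positive)",
                                         sum(object@labels)) else "unlabeled",
      "\n")
})

setMethod("show", "Embedding", function(object) {
  cat("Embedding:", nrow(object@coords), "objects in", ncol(object@coords),
      "dims; method =", object@method)
  if (length(object@subset))
    cat("; subset of", length(object@subset), "features")
  if (length(object@strength))
    cat(sprintf("; strength = %.4f", object@strength))
  cat("\n")
})

setMethod("show", "SubsetPlan", function(object) {
  cat("SubsetPlan:", length(object@subsets), "subsets of", object@V,
      "features from", object@N, "(seed", paste0(object@seed, ")"), "\n")
})

setMethod("show", "DistanceStack", function(object) {
  cat("DistanceStack:", length(object@matrices), "matrices of",
      nrow(object@consensus), "x", ncol(object@consensus),
      "; estimator =", object@estimator, "\n")
})

setMethod("show", "ConsensusResult", function(object) {
  cat("ConsensusResult:", nrow(object@embedding@coords), "objects in",
      ncol(object@embedding@coords), "dims from",
      length(object@stack@matrices), "selected embeddings;",
      sprintf("stress = %.4g", object@stress), "\n")
})

setMethod("show", "SubsampleMap", function(object) {
  cat("SubsampleMap:", length(object@assignment), "objects ->",
      nrow(object@repCoords), "representatives",
      sprintf("(t = %.1f, bandwidth = %.4g)",
              length(object@assignment) / nrow(object@repCoords),
              object@bandwidth), "\n")
})

setMethod("show", "Partition", function(object) {
  cat("Partition:", length(object@labels), "objects in", object@k, "clusters")
  if (length(object@accuracy))
    cat(sprintf("; accuracy = %.4f", object@accuracy))
  cat("\n")
})

setMethod("show", "TripletStats", function(object) {
  cat(sprintf("TripletStats: psi = %.4f (%s/%s triplets preserved%s)\n",
              object@psi, format(object@preserved, big.mark = ","),
              format(object@Z, big.mark = ","),
              if (object@sampled) ", sampled" else ""))
})

setMethod("show", "ClassTripletStats", function(object) {
  cat(sprintf(
    "ClassTripletStats: phi = %.4f over U = %s class triplets (Y = %s, Z = %s)\n",
    object@phiAccTriplet, format(object@U, big.mark = ","),
    format(object@Y, big.mark = ","), format(object@Z, big.mark = ",")))
})
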