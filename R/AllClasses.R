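#' @useDynLib ConsensusEmbed, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' FeatureSet: objects described by real-valued features
#'
#' Container for an R x N object-by-feature matrix (objects in rows), with
#' optional binary class labels. Pixel-level feature extraction and the
#' synthetic generators all return this class; it is the input to every
#' embedding routine.
#'
#' @slot values numeric matrix, R objects x N features; no missing values.
#' @slot labels integer vector of length 0 (unlabeled) or R with values in
#'   \{0, 1\}.
#'
#' @aliases FeatureSet-class
#' @exportClass FeatureSet
setClass("FeatureSet",
  slots = c(values = "matrix", labels = "integer"),
  prototype = prototype(values = matrix(numeric(0), 0, 0), labels = integer(0))
)

setValidity("FeatureSet", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("'values' must be a numeric matrix")
  if (anyNA(v) || any(!is.finite(v))) return("'values' must be finite with no NAs")
  l <- object@labels
  if (length(l) && length(l) != nrow(v))
    return("'labels' must be empty or one per object (row)")
  if (length(l) && !all(l %in% c(0L, 1L)))
    return("'labels' must be binary (0/1)")
  TRUE
})

#' Construct a FeatureSet
#'
#' @param values numeric matrix, objects in rows.
#' @param labels optional binary (0/1) vector, one per row.
#' @return A \linkS4class{FeatureSet}.
#' @examples
#' fs <- FeatureSet(matrix(rnorm(20), 5, 4), labels = c(0, 0, 1, 1, 1))
#' @export
FeatureSet <- function(values, labels = integer(0)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colnames(values)))
    colnames(values) <- paste0("f", seq_len(ncol(values)))
  new("FeatureSet", values = values, labels = as.integer(labels))
}

#' Embedding: a low-dimensional coordinate representation
#'
#' Result of applying a dimensionality-reduction method to a
#' \linkS4class{FeatureSet} (or of projecting a consensus distance matrix).
#' Carries provenance: the DR method tag, the feature subset it was computed
#' from (empty for direct DR on all features), and, once evaluated, its
#' embedding strength.
#'
#' @slot coords numeric matrix, R objects x n embedding coordinates.
#' @slot method character tag, e.g. "pca", "ge", "mds".
#' @slot subset integer indices of the source features used (may be empty).
#' @slot strength numeric of length 0 or 1; embedding strength once scored.
#' @slot id integer of length 0 or 1; index within an ensemble.
#'
#' @aliases Embedding-class
#' @exportClass Embedding
setClass("Embedding",
  slots = c(coords = "matrix", method = "character", subset = "integer",
            strength = "numeric", id = "integer"),
  prototype = prototype(coords = matrix(numeric(0), 0, 0), method = NA_character_,
                        subset = integer(0), strength = numeric(0), id = integer(0))
)

setValidity("Embedding", function(object) {
  if (anyNA(object@coords) || any(!is.finite(object@coords)))
    return("'coords' must be finite")
  if (length(object@strength) > 1) return("'strength' must have length 0 or 1")
  TRUE
})

Embedding <- function(coords, method = NA_character_, subset = integer(0),
                      strength = numeric(0), id = integer(0)) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  new("Embedding", coords = coords, method = as.character(method),
      subset = as.integer(subset), strength = as.numeric(strength),
      id = as.integer(id))
}

#' SubsetPlan: bootstrapped feature subspaces for ensemble generation
#'
#' M feature subsets of V indices each, drawn so that every one of the N
#' source features is covered by at least one subset.
#'
#' @slot subsets list of M integer vectors, each of V distinct indices.
#' @slot N integer, total feature count.
#' @slot V integer, subset size (V < N).
#' @slot seed integer seed the plan was drawn with.
#'
#' @aliases SubsetPlan-class
#' @exportClass SubsetPlan
setClass("SubsetPlan",
  slots = c(subsets = "list", N = "integer", V = "integer", seed = "integer"))

setValidity("SubsetPlan", function(object) {
  if (!all(vapply(object@subsets, function(s)
        length(s) == object@V && !anyDuplicated(s) &&
        all(s >= 1L & s <= object@N), logical(1))))
    return("each subset must hold V distinct indices in 1..N")
  if (!all(seq_len(object@N) %in% unlist(object@subsets)))
    return("every feature must appear in at least one subset")
  TRUE
})

#' DistanceStack: normalized pairwise-distance matrices plus their consensus
#'
#' K symmetric R x R matrices (one per selected embedding, each scaled to a
#' maximum entry of 1) together with the consensus matrix obtained by taking
#' the elementwise median or mean across the stack.
#'
#' @slot matrices list of K numeric R x R matrices.
#' @slot consensus numeric R x R matrix.
#' @slot estimator character, "median" or "mean".
#'
#' @aliases DistanceStack-class
#' @exportClass DistanceStack
setClass("DistanceStack",
  slots = c(matrices = "list", consensus = "matrix", estimator = "character"))

setValidity("DistanceStack", function(object) {
  dims <- vapply(object@matrices, dim, integer(2))
  if (length(object@matrices) == 0) return("stack must hold at least 1 matrix")
  if (any(dims != dims[1])) return("all matrices must share one shape")
  if (!object@estimator %in% c("median", "mean"))
    return("'estimator' must be 'median' or 'mean'")
  TRUE
})

#' ConsensusResult: the fused embedding and its provenance
#'
#' @slot embedding the consensus \linkS4class{Embedding}.
#' @slot stack the \linkS4class{DistanceStack} it was projected from.
#' @slot selectedIds integer ids of the selected (strong) base embeddings.
#' @slot stress normalized residual between the consensus distance matrix and
#'   the pairwise distances of the projected embedding.
#'
#' @aliases ConsensusResult-class
#' @exportClass ConsensusResult
setClass("ConsensusResult",
  slots = c(embedding = "Embedding", stack = "DistanceStack",
            selectedIds = "integer", stress = "numeric"))

#' SubsampleMap: mean-shift reduction of objects to representatives
#'
#' @slot repCoords numeric matrix of representative (mode) feature vectors.
#' @slot assignment integer of length R mapping each original object to a
#'   representative row.
#' @slot bandwidth numeric kernel bandwidth used.
#'
#' @aliases SubsampleMap-class
#' @exportClass SubsampleMap
setClass("SubsampleMap",
  slots = c(repCoords = "matrix", assignment = "integer", bandwidth = "numeric"))

setValidity("SubsampleMap", function(object) {
  if (length(object@assignment) &&
      !all(seq_len(nrow(object@repCoords)) %in% object@assignment))
    return("'assignment' must be surjective onto the representatives")
  if (any(object@assignment < 1L | object@assignment > nrow(object@repCoords)))
    return("'assignment' out of range")
  TRUE
})

#' Partition: a clustering of objects
#'
#' @slot labels integer cluster ids, one per object.
#' @slot k integer number of clusters.
#' @slot inertia numeric within-cluster sum of squares (where defined).
#' @slot accuracy numeric of length 0 or 1; cluster-overlap classification
#'   accuracy against ground truth, when evaluated.
#'
#' @aliases Partition-class
#' @exportClass Partition
setClass("Partition",
  slots = c(labels = "integer", k = "integer", inertia = "numeric",
            accuracy = "numeric"),
  prototype = prototype(inertia = NA_real_, accuracy = numeric(0)))

setValidity("Partition", function(object) {
  if (any(is.na(object@labels))) return("cluster labels must not be NA")
  if (object@k < 1L) return("'k' must be >= 1")
  TRUE
})

#' TripletStats: triplet-preservation summary of an embedding
#'
#' @slot Z numeric, number of unique triplets considered (C(R,3) when exact).
#' @slot preserved numeric, count with the triangle relationship preserved.
#' @slot psi numeric, embedding strength preserved / Z.
#' @slot sampled logical, TRUE when triplets were sampled rather than
#'   enumerated.
#' @slot sampleSize integer (length 0 unless sampled).
#' @slot seed integer (length 0 unless sampled).
#'
#' @aliases TripletStats-class
#' @exportClass TripletStats
setClass("TripletStats",
  slots = c(Z = "numeric", preserved = "numeric", psi = "numeric",
            sampled = "logical", sampleSize = "integer", seed = "integer"))

setValidity("TripletStats", function(object) {
  if (object@psi < 0 || object@psi > 1) return("'psi' must lie in [0,1]")
  TRUE
})

#' ClassTripletStats: triplet-level classification accuracy summary
#'
#' @slot Z numeric, total unique triplets.
#' @slot U numeric, class triplets (labels not all equal).
#' @slot Y numeric, non-class triplets.
#' @slot preservedL numeric, class triplets preserved in the embedding.
#' @slot phiAccTriplet numeric, preservedL / U.
#'
#' @aliases ClassTripletStats-class
#' @exportClass ClassTripletStats
setClass("ClassTripletStats",
  slots = c(Z = "numeric", U = "numeric", Y = "numeric",
            preservedL = "numeric", phiAccTriplet = "numeric"))
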