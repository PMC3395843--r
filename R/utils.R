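# internal helpers shared across modules

.mat <- function(x) {
  if (is(x, "FeatureSet")) return(x@values)
  if (is(x, "Embedding")) return(x@coords)
  if (is(x, "ConsensusResult")) return(x@embedding@coords)
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  m
}

.labels <- function(x) {
  if (is(x, "FeatureSet")) return(x@labels)
  integer(0)
}

# fix eigen/loading sign so results are platform-reproducible: the entry of
# largest magnitude in each column is made positive (ties broken by position)
.fixSigns <- function(coords, reference = coords) {
  for (j in seq_len(ncol(coords))) {
    v <- reference[, j]
    i <- which.max(abs(v))
    if (length(i) && v[i] < 0) coords[, j] <- -coords[, j]
  }
  coords
}

.withSeed <- function(seed, code) {
  if (is.null(seed) || !length(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

# derive a stream of child seeds below 2^31 from one master seed
.childSeeds <- function(seed, n) {
  .withSeed(seed, sample.int(.Machine$integer.max, n))
}
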