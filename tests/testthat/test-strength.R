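test_that("triangle relationship follows the closest-pair definition", {
  expect_identical(triangleRelationship(c(1, 2, 3), c(10, 20, 30)), 1L)
  expect_identical(triangleRelationship(c(1, 2, 3), c(3, 2, 1)), 0L)
  # the anchor pair (cd) must stay minimal; the other two may swap
  expect_identical(triangleRelationship(c(1, 2, 3), c(1, 3, 2)), 1L)
  # tied high-d anchor: preserved iff no strict inequality is violated
  expect_identical(triangleRelationship(c(1, 1, 2), c(1, 1, 2)), 1L)
  expect_identical(triangleRelationship(c(1, 1, 2), c(2, 2, 1)), 0L)
  expect_identical(triangleRelationship(c(1, 1, 1), c(5, 2, 9)), 1L)
})

test_that("embedding strength is exactly 1 for isometric embeddings", {
  withr::with_seed(1, X <- matrix(rnorm(12 * 4), 12))
  withr::with_seed(2, Q <- qr.Q(qr(matrix(rnorm(16), 4))))
  iso <- X %*% Q + rep(3, each = 12)          # rotation + translation
  expect_equal(strength(embeddingStrength(X, iso)), 1)
  # 1-D reflection preserves all distances
  x1 <- cbind(c(0, 1, 2, 10))
  expect_equal(strength(embeddingStrength(x1, -x1)), 1)
})

test_that("embedding strength equals exhaustive enumeration", {
  ts <- embeddingStrength(cbind(c(0, 1, 2, 10)), cbind(c(0, 1, 2, 2.5)))
  oracle <- naiveStrength(cbind(c(0, 1, 2, 10)), cbind(c(0, 1, 2, 2.5)))
  expect_equal(ts@Z, 4)
  expect_equal(ts@preserved, unname(oracle["preserved"]))
  withr::with_seed(3, {
    Xh <- matrix(rnorm(10 * 5), 10)
    Xl <- matrix(rnorm(10 * 2), 10)
  })
  o <- naiveStrength(Xh, Xl)
  s <- embeddingStrength(Xh, Xl)
  expect_equal(s@psi, unname(o["preserved"] / o["total"]))
  expect_error(embeddingStrength(Xh[1:2, ], Xl[1:2, ]), "3 objects")
  expect_error(embeddingStrength(Xh, Xl[1:9, ]), "differ")
})

test_that("sampled strength converges to the exact value", {
  withr::with_seed(4, {
    Xh <- matrix(rnorm(60 * 6), 60)
    Xl <- matrix(rnorm(60 * 2), 60)
  })
  exact <- strength(embeddingStrength(Xh, Xl, maxExactR = 200))
  for (s in 1:20) {
    samp <- embeddingStrength(Xh, Xl, maxExactR = 10, sampleSize = 5e4,
                              seed = s)
    expect_true(samp@sampled)
    expect_lt(abs(strength(samp) - exact), 0.01)
  }
})

test_that("class-triplet counting matches exhaustive enumeration", {
  expect_equal(countClassTriplets(2, 2), c(Z = 4, Y = 0, U = 4))
  expect_equal(countClassTriplets(3, 0), c(Z = 1, Y = 1, U = 0))
  expect_equal(countClassTriplets(3, 3), c(Z = 20, Y = 2, U = 18))
  # brute-force check on labeled objects
  lab <- c(0, 0, 0, 1, 1, 1, 1)
  cnt <- 0
  for (c in 1:5) for (d in (c + 1):6) for (e in (d + 1):7)
    if (length(unique(lab[c(c, d, e)])) > 1) cnt <- cnt + 1
  expect_equal(unname(countClassTriplets(3, 4)["U"]), cnt)
  expect_error(countClassTriplets(1, 1), "at least 3")
})

test_that("triplet accuracy is 1 for two distant tight clusters", {
  b <- makeBlobs(nPer = 6, d = 3, sep = 20, seed = 5)
  ta <- tripletAccuracy(b$X, b$labels)
  expect_equal(ta@phiAccTriplet, 1)
  expect_equal(ta@U + ta@Y, ta@Z)
  expect_error(tripletAccuracy(b$X, rep(0, 12)), "one class")
})

test_that("shuffled labels give chance-level triplet accuracy", {
  withr::with_seed(6, X <- matrix(rnorm(20 * 2), 20))
  lab <- rep(c(0L, 1L), each = 10)
  phis <- vapply(1:100, function(s) {
    shuffled <- withr::with_seed(s, sample(lab))
    tripletAccuracy(X, shuffled)@phiAccTriplet
  }, numeric(1))
  expect_gt(mean(phis), 0.2)
  expect_lt(mean(phis), 0.45)
})

test_that("embedding strength dominates class-triplet accuracy under the class premise", {
  # Premise: same-label pairs are strictly the closest pair of every class
  # triplet in the source space; then preserved class triplets are a subset
  # of preserved triplets and psi * Z >= phi * U must hold on any embedding.
  for (s in 1:50) {
    pd <- makePremiseData(nPer = 6, d = 3, seed = s)
    withr::with_seed(1000 + s, Xl <- matrix(rnorm(12 * 2), 12))
    psi <- strength(embeddingStrength(pd$X, Xl))
    ta <- tripletAccuracy(Xl, pd$labels)
    expect_gte(psi + 1e-12, ta@phiAccTriplet * ta@U / ta@Z)
  }
})

test_that("cluster-overlap accuracy matches hand-worked cases", {
  truth <- c(1, 1, 0, 0)
  expect_equal(clusterAccuracy(c(1, 1, 2, 2), truth), 1)
  expect_equal(clusterAccuracy(c(1, 1, 1, 2), truth), 0.75)
  expect_equal(clusterAccuracy(c(1, 2, 1, 2), truth), 0.5)
  # invariant to cluster-id permutation
  expect_equal(clusterAccuracy(c(2, 2, 1, 1), truth), 1)
  # weighted form: weights replicate objects
  expect_equal(clusterAccuracy(c(1, 2), c(1, 0), weights = c(3, 1)),
               clusterAccuracy(c(1, 1, 1, 2), c(1, 1, 1, 0)))
})

test_that("R-squared index matches hand computation and its bounds", {
  x <- matrix(c(0, 1, 10, 11))
  expect_equal(rsIndex(x, c(1, 1, 2, 2)), 100 / 101, tolerance = 1e-12)
  expect_equal(rsIndex(x, rep(1, 4)), 0)              # T = 1: SSW = SST
  expect_equal(rsIndex(x, 1:4), 1)                    # singletons: SSW = 0
  expect_warning(v <- rsIndex(matrix(1, 4, 2), c(1, 1, 2, 2)), "SST")
  expect_equal(v, 0)
  b <- makeBlobs(seed = 7)
  expect_gt(unsupervisedStrength(b$X, k = 2), 0.9)
})

test_that("supervised strength recovers separable structure", {
  b <- makeBlobs(nPer = 10, d = 4, sep = 10, seed = 8)
  expect_equal(supervisedStrength(b$X, b$labels), 1)
})

test_that("strong-embedding selection applies both threshold modes", {
  embs <- lapply(1:3, function(i) Embedding(matrix(rnorm(10), 5)))
  psi <- c(0.9, 0.5, 0.1)
  litteral <- selEmbed(embs, strengths = psi, thetaMode = "factor-of-max",
                       thetaFactor = 0.15)
  expect_identical(litteral$Q, c(1L, 2L))       # theta = 0.135 excludes 0.1
  within <- selEmbed(embs, strengths = psi, thetaMode = "within-of-max",
                     thetaFactor = 0.15)
  expect_identical(within$Q, 1L)                # theta = 0.765
  allEq <- selEmbed(embs, strengths = c(0.4, 0.4, 0.4),
                    thetaMode = "factor-of-max")
  expect_identical(allEq$Q, 1:3)
  # factor 1 under the literal rule demands strictly-above-max: empty
  expect_error(selEmbed(embs, strengths = psi, thetaMode = "factor-of-max",
                        thetaFactor = 1), "lower")
  expect_equal(strength(litteral$embeddings[[1]]), 0.9)
})
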