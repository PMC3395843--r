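test_that("pairwise distances are symmetric with hand-checkable entries", {
  expect_equal(pairwiseDistances(matrix(5)), matrix(0, 1, 1))
  D <- pairwiseDistances(cbind(c(0, 3, 4)))
  expect_equal(D[1, 2], 3); expect_equal(D[1, 3], 4); expect_equal(D[2, 3], 1)
  withr::with_seed(1, X <- matrix(rnorm(30), 10))
  D <- pairwiseDistances(X)
  expect_identical(D, t(D))
  expect_true(all(diag(D) == 0))
})

test_that("distance normalization is idempotent and scale-invariant", {
  withr::with_seed(2, X <- matrix(rnorm(24), 8))
  W <- pairwiseDistances(X)
  Wn <- normalizeDistances(W)
  expect_equal(max(Wn), 1)
  expect_equal(Wn, W / max(W))
  expect_equal(normalizeDistances(Wn), Wn)
  expect_equal(normalizeDistances(W * 17), Wn)     # global scale removed
  expect_warning(normalizeDistances(matrix(0, 3, 3)), "all-zero")
})

test_that("ML combination takes the elementwise median or mean", {
  mk <- function(v) matrix(v, 2, 2)
  st <- list(mk(1), mk(2), mk(9))
  expect_equal(mlCombine(st, "median"), mk(2))
  expect_equal(mlCombine(st, "mean"), mk(4))
  expect_equal(mlCombine(st[c(2, 2, 2)], "median"), mk(2)) # identical members
  expect_error(mlCombine(list(mk(1), matrix(1, 3, 3))), "shape")
  # median resists one grossly corrupted member; mean does not
  withr::with_seed(3, X <- matrix(rnorm(20), 10))
  W <- normalizeDistances(pairwiseDistances(X))
  corrupted <- W + 50
  stack <- c(replicate(5, W, simplify = FALSE), list(corrupted))
  expect_equal(mlCombine(stack, "median"), W)
  expect_gt(max(abs(mlCombine(stack, "mean") - W)), 1)
})

test_that("consensus of one embedding degenerates to MDS of its distances", {
  withr::with_seed(4, e <- Embedding(matrix(rnorm(20), 10)))
  res <- calcConsEmbed(list(e), 2)
  direct <- classicalMDS(normalizeDistances(pairwiseDistances(e)), 2)
  expect_equal(coords(res), coords(direct), tolerance = 1e-10)
})

test_that("consensus of identical exact embeddings reproduces their geometry", {
  withr::with_seed(5, e <- Embedding(matrix(rnorm(12 * 3), 12)))
  res <- calcConsEmbed(rep(list(e), 10), 3)
  D0 <- normalizeDistances(pairwiseDistances(e))
  Dc <- pairwiseDistances(res)
  up <- upper.tri(D0)
  expect_lt(max(abs(Dc[up] - D0[up]) / max(D0)), 1e-6)
  expect_lt(res@stress, 1e-8)
})

test_that("consensus construction ignores the order of the selected embeddings", {
  withr::with_seed(6, embs <- lapply(1:5, function(i)
    Embedding(matrix(rnorm(16), 8))))
  a <- calcConsEmbed(embs, 2)
  b <- calcConsEmbed(rev(embs), 2)
  expect_equal(coords(a), coords(b), tolerance = 1e-12)
  expect_equal(consensusMatrix(a), consensusMatrix(b))
})

test_that("median consensus shrugs off one adversarial embedding", {
  b <- makeBlobs(nPer = 10, d = 6, sep = 10, seed = 7)
  good <- lapply(1:9, function(i) {
    withr::with_seed(i, jit <- matrix(rnorm(20 * 2, sd = 0.05), 20))
    Embedding(coords(pcaEmbed(b$X, 2)) + jit)
  })
  adv <- Embedding(coords(good[[1]])[withr::with_seed(99, sample(20)), ])
  accOf <- function(members) {
    cons <- calcConsEmbed(members, 2, "median")
    p <- replicatedKMeans(coords(cons), 2, seed = 1)
    clusterAccuracy(clusterLabels(p), b$labels)
  }
  expect_lte(abs(accOf(good) - accOf(c(good, list(adv)))), 0.02)
})

test_that("consensus success probability matches the binomial aggregate", {
  # oracle: explicit binomial sum over K = 1..M
  oracle <- function(a, M) sum(dbinom(1:M, M, a))
  for (a in c(0, 0.1, 0.3, 0.5, 0.8, 1))
    for (M in c(1, 2, 5, 20, 100))
      expect_equal(consensusSuccessProbability(a, M), oracle(a, M),
                   tolerance = 1e-12)
  expect_equal(consensusSuccessProbability(1, 7), 1)
  expect_equal(consensusSuccessProbability(0, 7), 0)
  expect_equal(consensusSuccessProbability(0.5, 2), 0.75)
  # monotone in both arguments, and never below the single-embedding rate
  al <- seq(0, 1, 0.05)
  for (M in c(1, 3, 10)) {
    p <- consensusSuccessProbability(al, M)
    expect_true(all(diff(p) >= -1e-12))
    expect_true(all(p >= al - 1e-12))
  }
  expect_true(all(diff(vapply(1:20, function(M)
    consensusSuccessProbability(0.3, M), numeric(1))) >= 0))
  expect_error(consensusSuccessProbability(1.2, 3), "alpha")
  expect_error(consensusSuccessProbability(0.5, 0), "M")
})

test_that("pairwise MSE averages squared differences over unordered pairs", {
  W <- matrix(1, 3, 3); diag(W) <- 0
  expect_equal(pairwiseMSE(W, W), 0)
  expect_equal(pairwiseMSE(W, matrix(0, 3, 3)), 1)  # 3 pairs, each error 1
  withr::with_seed(8, {
    A <- pairwiseDistances(matrix(rnorm(15), 5))
    B <- pairwiseDistances(matrix(rnorm(15), 5))
    perm <- sample(5)
  })
  expect_equal(pairwiseMSE(A[perm, perm], B[perm, perm]), pairwiseMSE(A, B))
  expect_error(pairwiseMSE(A, matrix(0, 4, 4)), "shapes")
})

test_that("mean-combined consensus error never exceeds the average member error", {
  withr::with_seed(9, ref <- pairwiseDistances(matrix(rnorm(12 * 3), 12)))
  # equality cases
  one <- prop2Check(ref, list(ref + 1))
  expect_equal(one$epsilonK, one$epsilonC)
  expect_true(one$holds)
  same <- prop2Check(ref, rep(list(ref * 2), 4))
  expect_equal(same$epsilonK, same$epsilonC)
  # 100 seeded random stacks: Jensen inequality on every draw
  for (s in 1:100) {
    stack <- withr::with_seed(s, lapply(1:7, function(k)
      pairwiseDistances(matrix(rnorm(12 * 3), 12))))
    expect_true(prop2Check(ref, stack)$holds)
  }
})
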