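test_that("PCA embedding recovers rank and ignores translation", {
  line <- cbind(1:6) %*% rbind(c(1, 2, -1))           # collinear 3-D points
  e <- pcaEmbed(line, 1)
  # rank-1 data: 1-D projection reconstructs all pairwise distances
  expect_equal(as.matrix(dist(coords(e))), as.matrix(dist(line)),
               tolerance = 1e-10)
  withr::with_seed(1, X <- matrix(rnorm(20 * 6), 20))
  expect_equal(coords(pcaEmbed(X, 3)),
               coords(pcaEmbed(X + rep(5, each = 20), 3)), tolerance = 1e-9)
  # full-rank embedding is an isometry of the centered data
  expect_equal(as.matrix(dist(coords(pcaEmbed(X, 6)))), as.matrix(dist(X)),
               tolerance = 1e-9)
  expect_error(pcaEmbed(X, 7), "must lie in")
})

test_that("graph embedding separates well-separated blobs and is isometry-invariant", {
  b <- makeBlobs(nPer = 10, d = 10, sep = 10, seed = 2)
  e <- graphEmbed(b$X, 1)
  side <- coords(e)[, 1] > median(coords(e)[, 1])
  expect_true(all(side[1:10] == side[1]) && all(side[11:20] == !side[1]))
  # duplicated rows get identical coordinates
  Xd <- b$X[c(1:20, 1, 7), ]
  ed <- graphEmbed(Xd, 2)
  expect_equal(coords(ed)[21, ], coords(ed)[1, ], tolerance = 1e-8)
  expect_equal(coords(ed)[22, ], coords(ed)[7, ], tolerance = 1e-8)
  # rigid rotation leaves the affinities, hence the embedding, unchanged
  withr::with_seed(3, Q <- qr.Q(qr(matrix(rnorm(100), 10))))
  expect_equal(coords(graphEmbed(b$X %*% Q, 2)), coords(graphEmbed(b$X, 2)),
               tolerance = 1e-7)
  expect_error(graphEmbed(b$X[1:2, ], 1), "n \\+ 2")
})

test_that("graph embedding is equivariant under object reordering", {
  b <- makeBlobs(nPer = 8, d = 6, sep = 6, seed = 4)
  perm <- withr::with_seed(5, sample(16))
  e1 <- coords(graphEmbed(b$X, 2))
  e2 <- coords(graphEmbed(b$X[perm, ], 2))
  expect_equal(e2, e1[perm, ], tolerance = 1e-7)
})

test_that("classical MDS reconstructs Euclidean configurations", {
  square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  D <- as.matrix(dist(square))
  e <- classicalMDS(D, 2)
  expect_equal(as.matrix(dist(coords(e))), D, tolerance = 1e-8)
  # all-zero distances: every point at the origin (no positive eigenvalues)
  expect_warning(z <- classicalMDS(matrix(0, 3, 3), 1), "padding")
  expect_true(all(abs(coords(z)) < 1e-10))
  # 1-D positions {0, 1, 3}: embedded gaps {1, 3} up to sign
  e1 <- classicalMDS(as.matrix(dist(c(0, 1, 3))), 1)
  gaps <- sort(abs(diff(coords(e1)[, 1])))
  expect_equal(gaps, c(1, 2), tolerance = 1e-8)
  expect_equal(abs(coords(e1)[3, 1] - coords(e1)[1, 1]), 3, tolerance = 1e-8)
  expect_error(classicalMDS(matrix(c(0, 1, 2, 0), 2), 1), "symmetric")
})

test_that("classical MDS agrees with the cmdscale reference on random data", {
  withr::with_seed(6, X <- matrix(rnorm(15 * 4), 15))
  D <- as.matrix(dist(X))
  ours <- coords(classicalMDS(D, 3))
  ref <- cmdscale(D, k = 3)
  expect_equal(abs(ours), abs(ref), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(as.matrix(dist(ours)), as.matrix(dist(ref)), tolerance = 1e-8)
})

test_that("MDS pads coordinates with zeros beyond the positive spectrum", {
  D <- as.matrix(dist(c(0, 1, 3)))   # 1-D configuration: 1 positive eigenvalue
  expect_warning(e <- classicalMDS(D, 3), "padding")
  expect_true(all(abs(coords(e)[, 3]) < 1e-8))
})

test_that("pipeline composition: MDS of pairwise distances is distance-preserving", {
  withr::with_seed(7, X <- matrix(rnorm(12 * 5), 12))
  e <- classicalMDS(pairwiseDistances(X), 5)
  expect_equal(as.matrix(dist(coords(e))), as.matrix(dist(X)),
               tolerance = 1e-8)
})

test_that("intrinsic dimension estimates match the generating rank", {
  withr::with_seed(8, {
    plane <- matrix(rnorm(50 * 2), 50) %*% matrix(rnorm(20), 2)  # rank 2 in 10-D
  })
  expect_identical(estimateIntrinsicDim(plane), 2L)
  hits <- 0
  withr::with_seed(99, B <- qr.Q(qr(matrix(rnorm(100), 10)))[, 1:5])
  for (s in 1:20) {
    withr::with_seed(s, iso <- matrix(rnorm(400 * 5), 400) %*% t(B))
    hits <- hits + (estimateIntrinsicDim(iso, 0.95) == 5L)
  }
  expect_gte(hits, 19)   # isotropic 5-D signal in a 10-D ambient space
  expect_identical(estimateIntrinsicDim(matrix(1, 12, 4)), 1L)  # degenerate
  expect_error(estimateIntrinsicDim(matrix(1, 5, 3)), "10")
})
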