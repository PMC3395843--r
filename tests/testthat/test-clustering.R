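test_that("replicated k-means recovers separated blobs reproducibly", {
  b <- makeBlobs(nPer = 20, d = 4, sep = 10, seed = 1)
  p <- replicatedKMeans(b$X, 2, seed = 2)
  expect_equal(clusterAccuracy(clusterLabels(p), b$labels), 1)
  p2 <- replicatedKMeans(b$X, 2, seed = 2)
  expect_identical(clusterLabels(p), clusterLabels(p2))
  # one cluster: inertia equals the total sum of squares
  one <- replicatedKMeans(b$X, 1)
  expect_equal(one@inertia, sum(scale(b$X, scale = FALSE)^2))
  expect_error(replicatedKMeans(b$X[1:3, ], 4), "exceeds")
})

test_that("replicated k-means inertia never worsens with more replicates", {
  withr::with_seed(3, X <- matrix(rnorm(60 * 2), 60))
  inertias <- vapply(c(1, 5, 15, 25), function(r)
    replicatedKMeans(X, 4, replicates = r, seed = 7)@inertia, numeric(1))
  expect_true(all(diff(inertias) <= 1e-9))  # nested seeded replicate sets
})

test_that("k-means on at most k distinct rows partitions by value", {
  X <- cbind(rep(c(0, 10), each = 3), 1)          # 2 distinct rows
  p <- replicatedKMeans(X, 2, seed = 1)
  expect_equal(p@inertia, 0)
  expect_length(unique(clusterLabels(p)), 2)
})

test_that("hierarchical clustering cuts to the requested partition", {
  b <- makeBlobs(nPer = 15, d = 3, sep = 12, seed = 4)
  p <- hierarchicalCluster(b$X, 2)
  expect_equal(clusterAccuracy(clusterLabels(p), b$labels), 1)
  singles <- hierarchicalCluster(b$X, 30)
  expect_length(unique(clusterLabels(singles)), 30)
  # a duplicated object pair merges before anything else
  Xd <- rbind(b$X, b$X[4, ])
  hc <- hclust(dist(Xd), method = "average")
  expect_setequal(abs(hc$merge[1, ]), c(4, 31))
  expect_error(hierarchicalCluster(b$X, 31), "exceeds")
})

test_that("the subspace kNN ensemble votes like its parts", {
  b <- makeBlobs(nPer = 20, d = 10, sep = 8, seed = 5)
  train <- FeatureSet(b$X, labels = b$labels)
  plan <- makeSubsetPlan(10, 12, 3, seed = 6)
  # a test object duplicating a training object gets its class
  res <- knnSubspaceEnsemble(train, b$X[c(1, 40), ], plan, k = 5)
  expect_identical(res$class, c(0L, 1L))
  expect_lt(res$probability[1], 0.5)
  expect_gt(res$probability[2], 0.5)
  # M identical subsets collapse to the single-subset kNN vote
  planSame <- new("SubsetPlan", subsets = rep(list(1:10), 3), N = 10L,
                  V = 10L, seed = 1L)
  one <- knnSubspaceEnsemble(train, b$X[1:4, ], planSame, k = 3)
  pred <- class::knn(b$X, b$X[1:4, ], factor(b$labels), k = 3, prob = TRUE)
  pwin <- attr(pred, "prob")
  expect_equal(one$probability, ifelse(pred == "1", pwin, 1 - pwin))
  expect_error(knnSubspaceEnsemble(train, b$X, plan, k = 41), "exceeds")
})

test_that("subspace kNN ensemble is usually at least as good as full-space kNN", {
  wins <- 0; total <- 40
  for (s in 1:total) {
    ex <- makeExpression(nPerClass = 20, nInformative = 5, nNoise = 45,
                         effectSize = 5, seed = s)
    X <- featureValues(ex$features); lab <- objectLabels(ex$features)
    tr <- seq(1, 40, 2); te <- seq(2, 40, 2)
    train <- FeatureSet(X[tr, ], labels = lab[tr])
    plan <- makeSubsetPlan(50, 25, 7, seed = s)
    ens <- knnSubspaceEnsemble(train, X[te, ], plan, k = 5)
    accEns <- mean(ens$class == lab[te])
    single <- class::knn(X[tr, ], X[te, ], factor(lab[tr]), k = 5)
    accSingle <- mean((single == "1") == (lab[te] == 1L))
    wins <- wins + (accEns >= accSingle)
  }
  expect_gte(wins / total, 0.8)
})

test_that("label maps are deterministic colorings that conserve cluster sizes", {
  lm <- renderLabelMap(c(1L, 1L, 2L, 2L), c(2, 2))
  expect_equal(dim(lm$image), c(2, 2, 3))
  # column-major layout: labels (1,1,2,2) fill the first column then the second
  expect_equal(lm$image[1, 1, ], lm$image[2, 1, ])
  expect_false(all(lm$image[1, 1, ] == lm$image[1, 2, ]))
  # swapped ids: same geometry, swapped colors (columns trade colors)
  sw <- renderLabelMap(c(2L, 2L, 1L, 1L), c(2, 2))
  expect_equal(sw$image[, , 1], lm$image[, 2:1, 1])
  withr::with_seed(7, lab <- sample(1:3, 24, replace = TRUE))
  lm3 <- renderLabelMap(lab, c(4, 6))
  for (id in 1:3) {
    col <- lm3$legend$color[lm3$legend$cluster == id]
    rgb <- grDevices::col2rgb(col) / 255
    hits <- sum(lm3$image[, , 1] == rgb[1] & lm3$image[, , 2] == rgb[2] &
                lm3$image[, , 3] == rgb[3])
    expect_equal(hits, sum(lab == id))
  }
  expect_error(renderLabelMap(lab, c(5, 5)), "match")
})
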