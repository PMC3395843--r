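test_that("noise-free toy image takes exactly the two colors and is separable", {
  toy <- makeToyRGB(height = 30, width = 30, noiseSigma = 0, seed = 1)
  expect_true(all(toy$image[, , 1] %in% c(90, 150)))
  expect_true(all(toy$image[, , 2] == 120))
  expect_true(all(toy$image[, , 3] == 120))
  expect_identical(as.integer(toy$image[, , 1] == 150), as.vector(toy$labels))
  # k-means on the R channel alone recovers the classes exactly
  p <- replicatedKMeans(matrix(as.vector(toy$image[, , 1])), 2, seed = 1)
  expect_equal(clusterAccuracy(clusterLabels(p), as.vector(toy$labels)), 1)
})

test_that("toy noise corrupts only the chromatic channels", {
  toy <- makeToyRGB(height = 40, width = 40, noiseSigma = 40, seed = 2)
  clean <- makeToyRGB(height = 40, width = 40, noiseSigma = 0, seed = 2)
  expect_identical(toy$image[, , 1], clean$image[, , 1])   # R untouched
  expect_gt(sd(toy$image[, , 2] - clean$image[, , 2]), 30)
  expect_true(all(toy$image >= 0 & toy$image <= 255))
  # classes share G and B means: empirical class-mean gap ~ 0 there, 60 in R
  fg <- toy$labels == 1
  expect_lt(abs(mean(toy$image[, , 2][fg]) - mean(toy$image[, , 2][!fg])), 10)
  expect_equal(abs(mean(toy$image[, , 1][fg]) - mean(toy$image[, , 1][!fg])), 60)
})

test_that("toy generation is a pure function of its spec", {
  a <- makeToyRGB(seed = 7)
  b <- makeToyRGB(seed = 7)
  expect_identical(a$image, b$image)
  expect_identical(a$labels, b$labels)
  expect_false(identical(a$image, makeToyRGB(seed = 8)$image))
  expect_error(makeToyRGB(fgColor = c(90, 0, 0), bgColor = c(90, 9, 9)),
               "R channel")
  expect_error(makeToyRGB(height = 0), "positive")
  expect_error(makeToyRGB(noiseSigma = -1), ">= 0")
})

test_that("clean phantom is two-valued and threshold-separable", {
  ph <- makePhantom(noisePct = 0, biasPct = 0, seed = 1)
  expect_setequal(unique(as.vector(ph$image)), c(100, 130))
  thr <- as.integer(ph$image < 115)  # class 1 is the darker tissue
  expect_equal(mean(thr == ph$labels), 1)
})

test_that("bias-only phantom reproduces its returned field exactly", {
  ph <- makePhantom(noisePct = 0, biasPct = 40, seed = 1)
  expect_equal(ph$image / ph$noiseless, ph$bias, tolerance = 1e-12)
  expect_equal(mean(ph$bias), 1, tolerance = 1e-12)
  expect_equal((max(ph$bias) - mean(ph$bias)) / mean(ph$bias), 0.4,
               tolerance = 1e-10)
  expect_true(all(ph$bias > 0))
})

test_that("phantom noise magnitude matches its declared level", {
  ph <- makePhantom(height = 128, width = 128, noisePct = 9, biasPct = 0,
                    seed = 3)
  resid <- ph$image - ph$noiseless * ph$bias
  target <- 0.09 * mean(ph$noiseless)
  expect_lt(abs(sd(resid) - target) / target, 0.05)  # >= 10^4 pixels
})

test_that("phantom levels outside the study grid need an override", {
  expect_error(makePhantom(noisePct = 2), "grid")
  expect_error(makePhantom(biasPct = 10), "grid")
  expect_silent(makePhantom(noisePct = 2, biasPct = 10, allowAnyLevel = TRUE))
  expect_error(makePhantom(classMeans = c(100, 100)), "distinct")
})

test_that("null-effect expression features give null t statistics", {
  exceed <- 0; total <- 0
  for (s in 1:50) {
    ex <- makeExpression(nPerClass = 25, nInformative = 5, nNoise = 95,
                         effectSize = 0, seed = s)
    t <- welchT(ex$features)
    exceed <- exceed + sum(abs(t) > 3)
    total <- total + length(t)
  }
  expect_lt(exceed / total, 0.01)
})

test_that("strong-effect informative features rank above all noise features", {
  wins <- 0
  for (s in 1:100) {
    ex <- makeExpression(nPerClass = 50, nInformative = 5, nNoise = 95,
                         effectSize = 5, seed = s)
    top5 <- tStatPrune(ex$features, 5)$kept
    wins <- wins + identical(top5, ex$informative)
  }
  expect_gte(wins, 99)
})

test_that("expression generator contracts hold", {
  ex <- makeExpression(nPerClass = 10, nInformative = 4, nNoise = 0, seed = 1)
  expect_identical(ex$informative, 1:4)            # no noise: all informative
  a <- makeExpression(seed = 5); b <- makeExpression(seed = 5)
  expect_identical(featureValues(a$features), featureValues(b$features))
  expect_error(makeExpression(effectSize = -1), ">= 0")
  expect_error(makeExpression(nPerClass = 0), "positive")
})
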