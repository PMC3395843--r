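# Independent naive-loop oracles. These deliberately share no code with the
# package internals: plain double loops, recomputed per call.

# reflect index (no edge repeat), 1-based
reflect1 <- function(i, n) {
  if (n == 1) return(1L)
  period <- 2L * n - 2L
  j <- ((i - 1L) %% period + period) %% period
  if (j < n) j + 1L else period - j + 1L
}

# naive windowed first-order stats for one pixel
naiveFirstOrderPixel <- function(img, y, x, window) {
  r <- window %/% 2
  vals <- c()
  for (dx in -r:r)
    for (dy in -r:r)
      vals <- c(vals, img[reflect1(y + dy, nrow(img)), reflect1(x + dx, ncol(img))])
  c(mean(vals), median(vals), sd(vals), max(vals) - min(vals))
}

# naive symmetric normalized GLCM of the window patch around (y, x) for one
# offset; levels are the quantized values present in the patch
naiveGLCM <- function(q, y, x, window, dy, dx) {
  r <- window %/% 2
  patch <- matrix(0L, window, window)
  for (ix in 1:window)
    for (iy in 1:window)
      patch[iy, ix] <- q[reflect1(y + iy - r - 1L, nrow(q)),
                         reflect1(x + ix - r - 1L, ncol(q))]
  lv <- sort(unique(as.vector(patch)))
  G <- length(lv)
  glcm <- matrix(0, G, G)
  for (ix in 1:window)
    for (iy in 1:window) {
      qy <- iy + dy; qx <- ix + dx
      if (qy < 1 || qy > window || qx < 1 || qx > window) next
      a <- match(patch[iy, ix], lv); b <- match(patch[qy, qx], lv)
      glcm[a, b] <- glcm[a, b] + 1
      glcm[b, a] <- glcm[b, a] + 1
    }
  if (sum(glcm) > 0) glcm <- glcm / sum(glcm)
  list(p = glcm, levels = lv)
}

# the 14 Haralick statistics from one normalized symmetric GLCM (1-based
# gray-tone values = level + 1), written as direct formula transcriptions
naiveHaralick <- function(p, levels) {
  G <- length(levels)
  tone <- levels + 1
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(tone * px); muy <- sum(tone * py)
  sx <- sqrt(sum((tone - mux)^2 * px)); sy <- sqrt(sum((tone - muy)^2 * py))
  energy <- sum(p^2)
  contrast <- 0; corrnum <- 0; variance <- 0; idm <- 0; entropy <- 0
  hxy1 <- 0
  Lmax <- max(tone)
  psum <- rep(0, 2 * Lmax + 1)
  pdiff <- rep(0, Lmax + 1)
  for (i in 1:G) for (j in 1:G) {
    pij <- p[i, j]
    if (pij <= 0) next
    ti <- tone[i]; tj <- tone[j]
    contrast <- contrast + (ti - tj)^2 * pij
    corrnum <- corrnum + ti * tj * pij
    variance <- variance + (ti - mux)^2 * pij
    idm <- idm + pij / (1 + (ti - tj)^2)
    entropy <- entropy - pij * log(pij)
    if (px[i] * py[j] > 0) hxy1 <- hxy1 - pij * log(px[i] * py[j])
    psum[ti + tj + 1] <- psum[ti + tj + 1] + pij       # +1: R indexing
    pdiff[abs(ti - tj) + 1] <- pdiff[abs(ti - tj) + 1] + pij
  }
  ks <- which(psum > 0) - 1
  sumavg <- sum(ks * psum[ks + 1])
  sumvar <- sum((ks - sumavg)^2 * psum[ks + 1])
  sument <- -sum(psum[ks + 1] * log(psum[ks + 1]))
  kd <- which(pdiff > 0) - 1
  davg <- sum(kd * pdiff[kd + 1])
  dvar <- sum((kd - davg)^2 * pdiff[kd + 1])
  dent <- -sum(pdiff[kd + 1] * log(pdiff[kd + 1]))
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  hy <- -sum(py[py > 0] * log(py[py > 0]))
  hxy2 <- 0
  for (i in 1:G) for (j in 1:G)
    if (px[i] * py[j] > 0)
      hxy2 <- hxy2 - px[i] * py[j] * log(px[i] * py[j])
  correlation <- if (sx * sy > 1e-12) (corrnum - mux * muy) / (sx * sy) else 0
  imc1 <- if (max(hx, hy) > 1e-12) (entropy - hxy1) / max(hx, hy) else 0
  arg <- 1 - exp(-2 * (hxy2 - entropy))
  imc2 <- if (arg > 0) sqrt(arg) else 0
  mcc <- 0
  if (G >= 2 && all(px > 0)) {
    Q <- matrix(0, G, G)
    for (i in 1:G) for (j in 1:G)
      Q[i, j] <- sum(p[i, ] * p[j, ] / (px[i] * py))
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    mcc <- sqrt(min(max(ev[2], 0), 1))
  }
  c(energy, contrast, correlation, variance, idm, sumavg, sumvar, sument,
    entropy, dvar, dent, imc1, imc2, mcc)
}

# per-pixel Haralick features by brute force (features averaged over offsets)
naiveHaralickPixel <- function(q, y, x, window, offsets) {
  acc <- rep(0, 14)
  for (o in seq_len(nrow(offsets))) {
    g <- naiveGLCM(q, y, x, window, offsets[o, 1], offsets[o, 2])
    acc <- acc + naiveHaralick(g$p, g$levels)
  }
  acc / nrow(offsets)
}

# naive triplet preservation count over all C(R,3) triplets
naiveStrength <- function(Xh, Xl) {
  Dh <- as.matrix(dist(Xh)); Dl <- as.matrix(dist(Xl))
  R <- nrow(Dh)
  preserved <- 0; total <- 0
  for (c in 1:(R - 2)) for (d in (c + 1):(R - 1)) for (e in (d + 1):R) {
    hi <- c(Dh[c, d], Dh[c, e], Dh[d, e])
    lo <- c(Dl[c, d], Dl[c, e], Dl[d, e])
    total <- total + 1
    mn <- which(hi == min(hi))
    if (length(mn) == 1) {
      if (all(lo[mn] < lo[-mn])) preserved <- preserved + 1
    } else {
      ok <- TRUE
      for (a in 1:3) for (b in 1:3)
        if (hi[a] < hi[b] && lo[a] >= lo[b]) ok <- FALSE
      if (ok) preserved <- preserved + 1
    }
  }
  c(preserved = preserved, total = total)
}

# two well-separated Gaussian blobs with labels
makeBlobs <- function(nPer = 10, d = 5, sep = 10, seed = 1) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(nPer * d), nPer),
               matrix(rnorm(nPer * d) + sep, nPer))
  })
  list(X = X, labels = rep(c(0L, 1L), each = nPer))
}

# labeled high-d data satisfying the class-triplet premise: same-label pairs
# are strictly the closest pair of every class triplet
makePremiseData <- function(nPer = 8, d = 4, seed = 1) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(nPer * d, sd = 0.5), nPer),
               matrix(rnorm(nPer * d, sd = 0.5) + 50, nPer))
  })
  list(X = X, labels = rep(c(0L, 1L), each = nPer))
}
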