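glmDesign <- function(nVolumes = 150) {
  set.seed(55)
  ev <- data.frame(onset = seq(8, nVolumes * 2 - 20, by = 9))
  n <- nrow(ev)
  ev$entropy <- runif(n, 0, 0.25)
  ev$surprisal <- runif(n, 0, 1.4)
  ev$step_duration <- runif(n, 2, 6)
  buildDesign(ev, nVolumes = nVolumes)
}

test_that("noiseless voxels are recovered essentially exactly", {
  d <- glmDesign()
  X <- designMatrix(d)
  set.seed(10)
  btrue <- rnorm(ncol(X))
  y <- X %*% btrue
  fit <- fitFirstLevel(matrix(y, ncol = 1), d)
  expect_lt(max(abs(fit@beta[, 1] - btrue)), 1e-8)
  # precoloring never changes the sign of a noiseless beta
  expect_equal(sign(fit@beta[abs(btrue) > 1e-6, 1]),
               sign(btrue[abs(btrue) > 1e-6]), ignore_attr = TRUE)
  # effective df is reduced below the nominal residual df
  expect_lt(fit@effDf, nrow(X) - ncol(X))
  expect_gt(fit@effDf, 0)
})

test_that("first-level estimates are unbiased under AR(1) noise", {
  d <- glmDesign(120)
  X <- designMatrix(d)
  bH <- 1.5
  signal <- X[, "entropy"] * bH
  set.seed(12)
  est <- replicate(200, {
    y <- signal + drop(seqBOLD:::arNoise(nrow(X), 1, 0.5, 0.3, 0.2))
    fitFirstLevel(matrix(y, ncol = 1), d)@beta["entropy", 1]
  })
  expect_lt(abs(mean(est) - bH), 3 * sd(est) / sqrt(200))
})

test_that("a duplicated modulator column raises a rank-deficiency error", {
  d <- glmDesign(80)
  d@X <- cbind(d@X, entropy_copy = d@X[, "entropy"])
  expect_error(fitFirstLevel(matrix(rnorm(nrow(d@X)), ncol = 1), d),
               "rank deficient")
})

test_that("group t and z maps follow the one-sample construction", {
  z0 <- groupTTest(matrix(0, 5, 4))
  expect_true(all(z0@tMap == 0))
  expect_true(all(z0@zMap == 0))
  expect_true(all(z0@flagged))
  # constant nonzero input: infinite t flagged, z guarded finite
  g1 <- groupTTest(matrix(1, 5, 3))
  expect_true(all(is.infinite(g1@tMap)))
  expect_true(all(is.finite(g1@zMap)))
  expect_true(all(g1@flagged))
  # hand-set 15 values: t = mean / (sd / sqrt(n)), z tail-matched
  set.seed(3)
  v <- rnorm(15)
  v <- (v - mean(v)) / sd(v) # exactly mean 0, sd 1
  v <- v + 0.5
  g <- groupTTest(matrix(v, ncol = 1))
  expect_equal(g@tMap[1, 1, 1], 0.5 / (1 / sqrt(15)), tolerance = 1e-12)
  expect_equal(g@tMap[1, 1, 1], 1.936, tolerance = 1e-3)
  expect_equal(g@zMap[1, 1, 1],
               qnorm(pt(g@tMap[1, 1, 1], 14, lower.tail = FALSE),
                     lower.tail = FALSE), tolerance = 1e-12)
  expect_error(groupTTest(matrix(1, 1, 3)), "at least 2")
})

test_that("t and z maps share suprathreshold topology", {
  set.seed(9)
  M <- matrix(rnorm(12 * 64), 12, 64)
  g <- groupTTest(M, dim = c(4, 4, 4))
  # rank identity implies identical ordering
  expect_equal(order(g@tMap), order(g@zMap))
  qt <- quantile(g@tMap, 0.8)
  qz <- quantile(g@zMap, 0.8)
  expect_equal(g@tMap > qt, g@zMap > qz)
})

test_that("cluster labeling respects the connectivity scheme", {
  m <- array(FALSE, c(5, 5, 5))
  m[1, 1, 1] <- TRUE
  m[2, 2, 2] <- TRUE # diagonal neighbor of (1,1,1)
  m[5, 5, 5] <- TRUE
  lab26 <- seqBOLD:::labelClusters(m, 26)
  expect_equal(max(lab26), 2) # diagonal voxels merge under 26-connectivity
  lab6 <- seqBOLD:::labelClusters(m, 6)
  expect_equal(max(lab6), 3)  # but not under 6-connectivity
})

test_that("mc thresholds degenerate sensibly and grow with smoothness", {
  # smoothness 0 with a very high initial threshold: isolated voxels only
  thr <- mcClusterThresholds(c(12, 12, 12), smoothFwhmMm = 0,
                             initialZ = 5, iterations = 150, seed = 2)
  expect_equal(thr@sizeThreshold, 1)
  thrA <- mcClusterThresholds(c(14, 14, 14), smoothFwhmMm = 0,
                              iterations = 200, seed = 3)
  thrB <- mcClusterThresholds(c(14, 14, 14), smoothFwhmMm = 6,
                              iterations = 200, seed = 3)
  expect_gte(thrB@sizeThreshold, thrA@sizeThreshold)
  expect_gte(thrB@massThreshold, thrA@massThreshold)
  expect_error(mcClusterThresholds(c(4, 4, 4), smoothFwhmMm = 12,
                                   iterations = 100, seed = 1),
               "smaller than the smoothing kernel")
  expect_error(mcClusterThresholds(c(10, 10, 10), iterations = 10),
               "at least 100")
})

test_that("cluster correction keeps constructed blobs and little else", {
  thr <- new("ClusterThresholds", initialZ = 2.33, alpha = 0.05,
             sizeThreshold = 10, massThreshold = 30, iterations = 100L,
             smoothnessFwhmMm = 0, voxelSizeMm = 3, connectivity = 26L,
             rule = "and")
  z0 <- array(0, c(10, 10, 10))
  expect_equal(nrow(applyClusterCorrection(z0, thr)), 0)
  zb <- array(0, c(10, 10, 10))
  zb[3:6, 3:6, 3:5] <- 4 # 48-voxel blob at z = 4
  tab <- applyClusterCorrection(zb, thr)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$size, 48)
  expect_equal(tab$peak_z, 4)
  expect_equal(tab$mass, 192)
  # the "or" rule admits a small, heavy cluster that "and" rejects
  zs <- array(0, c(10, 10, 10))
  zs[5, 5, 5] <- 40
  expect_equal(nrow(applyClusterCorrection(zs, thr)), 0)
  thrOr <- thr
  thrOr@rule <- "or"
  expect_equal(nrow(applyClusterCorrection(zs, thrOr)), 1)
  expect_error(applyClusterCorrection(array(NaN, c(3, 3, 3)), thr),
               "finite")
})

test_that("null maps rarely survive their own corrected thresholds", {
  thr <- mcClusterThresholds(c(14, 14, 14), smoothFwhmMm = 5.65,
                             iterations = 300, seed = 4)
  set.seed(41)
  hits <- sum(replicate(60, {
    nrow(applyClusterCorrection(nullField(c(14, 14, 14), 5.65), thr)) > 0
  }))
  expect_lte(hits, 9) # >= 95% of seeds empty allowing binomial slack
})
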