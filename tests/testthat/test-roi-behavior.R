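test_that("the faces-mode ROI is the center plus six face neighbors", {
  roi <- ROISpec("left_anterior_hippocampus", c(-25, -16, -18))
  vox <- roiVoxels(roi, c(20, 20, 20), 3)
  expect_length(vox, 7)
  sub <- arrayInd(vox, c(20, 20, 20))
  ctr <- round(colMeans(sub))
  dist <- rowSums(abs(sweep(sub, 2, ctr)))
  expect_equal(sort(dist), c(0, 1, 1, 1, 1, 1, 1)) # connected, face-adjacent
  # radius mode as the alternative reading
  roiR <- ROISpec("r", c(0, 0, 0), mode = "radius", radiusMm = 3.1)
  expect_length(roiVoxels(roiR, c(20, 20, 20), 3), 7)
  expect_error(roiVoxels(ROISpec("out", c(40, 0, 0)), c(20, 20, 20), 3),
               "outside the grid")
})

test_that("ROI extraction averages correctly and recovers injections", {
  roi <- ROISpec("test", c(0, 0, 0))
  dims <- c(12, 12, 12)
  # constant map: ROI mean is that constant; zero maps give t = 0
  maps <- lapply(1:6, function(i) array(2.5, dims))
  ex <- extractRoiBetas(maps, roi, dim = dims)
  expect_equal(unname(ex$betas), rep(2.5, 6))
  z <- extractRoiBetas(lapply(1:5, function(i) array(0, dims)), roi,
                       dim = dims)
  expect_equal(z$t, 0)
  # injected effect exactly in the ROI voxels: significant recovery
  vox <- roiVoxels(roi, dims, 3)
  set.seed(6)
  maps2 <- lapply(1:15, function(i) {
    a <- array(rnorm(prod(dims), 0, 0.3), dims)
    a[vox] <- a[vox] + 1
    a
  })
  ex2 <- extractRoiBetas(maps2, roi, dim = dims)
  expect_lt(ex2$p, 0.05)
  expect_lt(abs(ex2$mean - 1), 0.1)
  expect_equal(ex2$df, 14)
})

test_that("post-test aggregation mirrors a hand computation", {
  d <- data.frame(
    participant = rep(1:3, each = 4),
    judgment = c(10, 30, 50, 90,   0, 20, 60, 100,  25, 25, 75, 75),
    true_level = rep(c(0, 0.25, 0.5, 1), 3))
  agg <- aggregatePostTest(d)
  expect_equal(agg$mean_judgment[agg$participant == 1],
               c(10, 30, 50, 90))
  # perfectly calibrated responder reproduces the levels
  perfect <- data.frame(participant = 1,
                        judgment = c(0, 25, 50, 75, 100),
                        true_level = c(0, 0.25, 0.5, 0.75, 1))
  expect_equal(aggregatePostTest(perfect)$mean_judgment,
               c(0, 25, 50, 75, 100))
  # permutation invariance over trials
  shuffled <- d[sample(nrow(d)), ]
  expect_equal(aggregatePostTest(shuffled), agg, ignore_attr = TRUE)
  expect_error(aggregatePostTest(data.frame(participant = 1, judgment = 1,
                                            true_level = NA)), "labeled")
  # scoring constants
  expect_equal(crossProbability(), 0.125)
  expect_equal(crossesToPercent(1), 12.5)
  expect_equal(crossesToPercent(8), 100)
})

test_that("familiarity follows its defining formula", {
  expect_equal(familiarity(c(100, 50, 0), c(100, 50, 0), 100), 100)
  # every judgment off by 20 points on the percent scale
  expect_equal(familiarity(c(80, 70, 20, 95, 80),
                           c(100, 50, 0, 75, 100), 100), 80)
  # uniform 50s against the five implemented levels: mean deviation 30
  expect_equal(familiarity(rep(50, 5), c(0, 25, 50, 75, 100), 100), 70)
  # crosses scale
  expect_equal(familiarity(c(8, 0, 4), c(8, 0, 4), 8), 8)
  expect_error(familiarity(c(50, 80), c(0.5, 0.8), 8), "scale mismatch")
  # strictly decreasing in any single deviation
  base <- familiarity(c(60, 40), c(50, 50), 100)
  worse <- familiarity(c(70, 40), c(50, 50), 100)
  expect_lt(worse, base)
})

test_that("synthetic responders produce valid post-test tables", {
  chain <- defaultChain()
  comp <- simulatePostTest(chain, nParticipants = 4, seed = 3)
  expect_equal(nrow(comp), 4 * 30)
  expect_true(all(comp$judgment >= 0 & comp$judgment <= 100))
  comp36 <- simulatePostTest(chain, nParticipants = 1,
                             includeRepeats = TRUE, seed = 3)
  expect_equal(nrow(comp36), 36)
  paper <- simulatePostTest(chain, nParticipants = 3, test = "paper",
                            seed = 4)
  sums <- tapply(paper$judgment, paste(paper$participant, paper$prev), sum)
  expect_true(all(sums == 8))
  # a noiseless responder is perfectly calibrated
  exact <- simulatePostTest(chain, nParticipants = 1, noiseSd = 0,
                            seed = 5)
  expect_equal(exact$judgment, exact$true_value)
  fam <- familiarityScores(exact, pMax = 100)
  expect_equal(fam$familiarity, 100)
})

test_that("beta-familiarity correlation reproduces its sampling theory", {
  expect_equal(correlateBetasFamiliarity(1:8, 1:8)$r, 1)
  set.seed(11)
  # linear generative link recovered within sampling error
  rGen <- 0.8
  reps <- replicate(200, {
    f <- rnorm(15)
    b <- rGen * f + sqrt(1 - rGen^2) * rnorm(15)
    correlateBetasFamiliarity(b, f)$r
  })
  expect_lt(abs(mean(reps) - rGen), 0.05)
  # type-I error calibration on independent vectors
  set.seed(12)
  pvals <- replicate(1000, correlateBetasFamiliarity(rnorm(10),
                                                     rnorm(10))$p)
  rate <- mean(pvals < 0.05)
  expect_lt(abs(rate - 0.05), 2 * sqrt(0.05 * 0.95 / 1000))
  # agreement with the standard test as an independent cross-check
  set.seed(13)
  b <- rnorm(12)
  f <- 0.5 * b + rnorm(12)
  ours <- correlateBetasFamiliarity(b, f)
  ref <- cor.test(b, f)
  expect_equal(ours$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  expect_error(correlateBetasFamiliarity(1:2, 1:2), "at least 3")
  expect_error(correlateBetasFamiliarity(rep(1, 5), 1:5), "zero variance")
})
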