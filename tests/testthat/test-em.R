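test_that("responsibilities normalize and degenerate grids are exact", {
  gt <- gaussianBlobVolume(16, sigma = 2.5, voxel = 2)
  set.seed(4)
  poses <- lapply(1:6, function(i) pose(quaternionToMatrix(rnorm(4))))
  ds <- makeToyDataset(gt, poses, noiseSd = 0.7, seed = 5)
  model <- forwardTransform(gt)
  ## one-pose grid: gamma identically 1
  g1 <- poseGridFromPoses(poses[1])
  es1 <- estep(ds, model, g1)
  expect_true(all(es1$gamma == 1))
  ## duplicated pose with equal priors: exact ties, gamma = 1/2
  g2 <- poseGridFromPoses(list(poses[[2]], poses[[2]]))
  es2 <- estep(ds, model, g2)
  expect_equal(as.vector(es2$gamma), rep(0.5, 12))
  ## generic grid: rows always sum to one
  g3 <- poseGridFromPoses(poses)
  es3 <- estep(ds, model, g3)
  expect_equal(rowSums(es3$gamma), rep(1, 6), tolerance = 1e-9)
})

test_that("E-step responsibilities match the brute-force likelihood", {
  n <- 8
  gt <- gaussianBlobVolume(n, sigma = 1.3, voxel = 2)
  rots <- latticeRotations()
  poses <- lapply(rots[c(2, 5, 9)], pose)
  ds <- makeToyDataset(gt, poses[c(1, 2)], noiseSd = 0.5, seed = 7)
  grid <- poseGridFromPoses(poses)
  model <- forwardTransform(gt)
  es <- estep(ds, model, grid)
  ## direct evaluation of the normalized Gaussian likelihoods
  sigma2 <- 0.25
  oracle <- matrix(0, 2, 3)
  for (i in 1:2) {
    lw <- vapply(1:3, function(g) {
      resid <- ds@images[, , i] - project(model, poses[[g]])
      -sum(Mod(resid)^2) / (2 * sigma2) + log(1 / 3)
    }, numeric(1))
    oracle[i, ] <- exp(lw - max(lw)) / sum(exp(lw - max(lw)))
  }
  expect_equal(es$gamma, oracle, tolerance = 1e-9)
})

test_that("the Gaussian M-step solves the per-voxel quadratic", {
  acc <- randomAccumulator(16, 2, seed = 8)
  ns <- 9
  ## tau^-2 = 0 (infinite signal power): unregularized map B/K
  xFree <- mstepGaussian(acc, shellProfile(rep(Inf, ns), "tau2"))
  expect_equal(xFree@data, acc@B / acc@K, tolerance = 1e-12)
  ## B = K elementwise with tau^-2 equal to K: x = 1/2
  accEq <- new("AccumulatorPair", B = acc@K + 0i, K = acc@K, voxelSize = 2)
  kConst <- array(0.8, dim(acc@K))
  accC <- new("AccumulatorPair", B = kConst + 0i, K = kConst, voxelSize = 2)
  xHalf <- mstepGaussian(accC, shellProfile(rep(1 / 0.8, ns), "tau2"))
  expect_equal(Re(xHalf@data), array(0.5, dim(kConst)), tolerance = 1e-12)
  expect_equal(max(Mod(Im(xHalf@data))), 0)
  ## tau2 = 0: full shrinkage to the prior mean
  xZero <- mstepGaussian(acc, shellProfile(rep(0, ns), "tau2"))
  expect_true(all(xZero@data == 0))
  ## random shells against dense 1-D numeric maximization per voxel
  set.seed(9)
  tau2 <- shellProfile(runif(ns, 0.5, 3), "tau2")
  x <- mstepGaussian(acc, tau2)
  k <- seq_len(16) - 1 - 8
  for (probe in list(c(9, 9, 9), c(4, 11, 7), c(9, 12, 9))) {
    s <- round(sqrt(sum(k[probe]^2)))
    tinv <- 1 / shellValues(tau2)[s + 1]
    Bv <- acc@B[probe[1], probe[2], probe[3]]
    Kv <- acc@K[probe[1], probe[2], probe[3]]
    obj <- function(re) -(Kv + tinv) * re^2 / 2 + Re(Conj(Bv)) * re
    est <- optimize(obj, c(-10, 10), maximum = TRUE)$maximum
    expect_equal(Re(x@data[probe[1], probe[2], probe[3]]), est,
                 tolerance = 1e-5)
  }
})

test_that("tau2 estimation follows the SSNR-times-power rule", {
  h <- randomFourierVolume(16, 2, seed = 10)
  ns <- 9
  ## identical half-maps: FSC clamps at 0.999
  t1 <- estimateTau2(h, h)
  pw <- shellValues(shellAverage(Mod(h@data)^2))
  expect_equal(shellValues(t1), 0.999 / 0.001 * pw, tolerance = 1e-9)
  ## anti-correlated half-maps: FSC -1 clamps to 0, tau2 = 0
  hNeg <- fourierVolume(-h@data, 2)
  expect_true(all(shellValues(estimateTau2(h, hNeg)) == 0))
  ## explicit zero-FSC shell
  f0 <- rep(0.5, ns); f0[4] <- 0
  t2 <- estimateTau2(h, h, fscOverride = f0)
  expect_equal(shellValues(t2)[4], 0)
  expect_gt(shellValues(t2)[3], 0)
})

test_that("MAP-EM never decreases the marginal log-posterior", {
  n <- 8
  gt <- gaussianBlobVolume(n, sigma = 1.4, voxel = 2)
  rots <- latticeRotations()
  gridPoses <- lapply(rots[seq_len(12)], pose)
  set.seed(11)
  dataPoses <- gridPoses[sample(12, 10, replace = TRUE)]
  ds <- makeToyDataset(gt, dataPoses, noiseSd = 1, seed = 12)
  grid <- poseGridFromPoses(gridPoses)
  tau2 <- shellProfile(pmax(shellValues(
    shellAverage(Mod(forwardTransform(gt)@data)^2)), 1e-4), "tau2")
  model <- forwardTransform(lowpassVolume(gt, 12))
  objs <- numeric(7)
  objs[1] <- emObjective(ds, model, grid, tau2)
  for (it in 1:6) {
    model <- emIterate(ds, model, grid, tau2)
    objs[it + 1] <- emObjective(ds, model, grid, tau2)
  }
  expect_true(all(diff(objs) > -1e-8))
  expect_gt(objs[7], objs[1])
})

test_that("half-set refinement is invariant to within-half permutations", {
  gt <- makePhantom(phantomSpec(side = 16, voxelSize = 3, seed = 14))
  ds <- simulateDataset(gt, 24, intensityScale = 0.5, noiseSd = 1,
                        seed = 15)
  grid <- poseGridUniform(12, 4)
  cfg <- refinementConfig(regularizer = "gaussian", grid = grid,
                          maxIterations = 2)
  run1 <- runRefinement(ds, cfg)
  ## permute images within half-set 1 (odd indices), keep half-set 2 fixed
  odd <- seq(1, 24, 2); even <- seq(2, 24, 2)
  perm <- integer(24)
  perm[odd] <- odd[c(5:12, 1:4)]
  perm[even] <- even
  run2 <- runRefinement(datasetSubset(ds, perm), cfg)
  for (k in 1:2)
    expect_equal(run1$final@halfModels[[k]]@data,
                 run2$final@halfModels[[k]]@data, tolerance = 1e-10)
})

test_that("RED refinement with lambda fixed at 0 equals the Gaussian run", {
  gt <- makePhantom(phantomSpec(side = 16, voxelSize = 3, seed = 19))
  ds <- simulateDataset(gt, 20, intensityScale = 0.5, noiseSd = 1,
                        seed = 20)
  grid <- poseGridUniform(10, 4)
  runG <- runRefinement(ds, refinementConfig(
    regularizer = "gaussian", grid = grid, maxIterations = 2))
  runR <- runRefinement(ds, refinementConfig(
    regularizer = "red", grid = grid, maxIterations = 2,
    denoiser = classicalDenoiser(2), lambdaFixed = 0))
  for (it in 1:2) for (k in 1:2)
    expect_identical(runR$states[[it]]@halfModels[[k]]@data,
                     runG$states[[it]]@halfModels[[k]]@data)
})

test_that("zero iterations return the initial reference", {
  gt <- makePhantom(phantomSpec(side = 16, voxelSize = 3, seed = 16))
  ds <- simulateDataset(gt, 8, intensityScale = 0.5, seed = 17)
  run <- runRefinement(ds, refinementConfig(regularizer = "gaussian",
                                            grid = poseGridUniform(6, 2),
                                            maxIterations = 0))
  expect_equal(run$final@iteration, 0L)
  ref0 <- forwardTransform(lowpassVolume(
    realVolume(gt@data * ds@intensityScale, 3), 30))
  expect_equal(run$final@halfModels[[1]]@data, ref0@data)
})

test_that("underflowing E-steps raise an error instead of NaN", {
  gt <- gaussianBlobVolume(16, sigma = 2, voxel = 2)
  ds <- makeToyDataset(gt, list(pose()), noiseSd = 0.5, seed = 18)
  grid <- poseGridFromPoses(list(pose()))
  huge <- fourierVolume(forwardTransform(gt)@data * 1e200, 2)
  expect_error(estep(ds, huge, grid), "underflow|NaN")
})
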