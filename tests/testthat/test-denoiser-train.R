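test_that("ground-truth coarsening is the stated spectral filter", {
  gt <- makePhantom(phantomSpec(side = 16, voxelSize = 3, seed = 51))
  ns <- 9
  expect_equal(coarsenGroundTruth(gt, rep(1, ns))@data, gt@data,
               tolerance = 1e-9)
  expect_lt(max(abs(coarsenGroundTruth(gt, rep(0, ns))@data)), 1e-12)
  ## step FSC: sharp low-pass, equals direct spectral masking
  f <- c(rep(1, 5), rep(0, ns - 5))
  got <- coarsenGroundTruth(gt, f)
  oracle <- inverseTransform(applyShellFilter(forwardTransform(gt), f))
  expect_equal(got@data, oracle@data, tolerance = 1e-12)
  ## composition: FSC1 then FSC2 equals the product filter
  set.seed(52)
  f1 <- runif(ns); f2 <- runif(ns)
  twice <- coarsenGroundTruth(coarsenGroundTruth(gt, f1), f2)
  once <- coarsenGroundTruth(gt, f1 * f2)
  expect_equal(twice@data, once@data, tolerance = 1e-9)
})

test_that("corpus construction counts pairs and logs resolutions", {
  specs <- list(phantomSpec(side = 16, voxelSize = 3, seed = 53))
  emc <- list(nImages = 20, maxIterations = 2,
              grid = poseGridUniform(8, 3))
  pairs <- buildTrainingCorpus(specs, snrTiers = 0.6, emConfig = emc,
                               seed = 54)
  expect_length(pairs, 2 * 2)  # two half-maps per iteration
  aug <- buildTrainingCorpus(specs, snrTiers = 0.6, emConfig = emc,
                             seed = 54, augment = 4)
  expect_length(aug, 2 * 2 * 4)
  ## nominal resolutions match an identical refinement re-run
  ph <- makePhantom(specs[[1]])
  ds <- simulateDataset(ph, 20, intensityScale = 0.6,
                        seed = cryored:::.subSeed(54, 1))
  run <- runRefinement(ds, refinementConfig(
    regularizer = "gaussian", grid = emc$grid, maxIterations = 2,
    keepIntermediates = TRUE))
  logRes <- vapply(run$states, function(s) s@nominalResolution, numeric(1))
  pairRes <- vapply(pairs, function(p) p@nominalResolution, numeric(1))
  expect_equal(sort(unique(pairRes)), sort(unique(logRes)),
               tolerance = 1e-9)
  ## determinism
  pairs2 <- buildTrainingCorpus(specs, snrTiers = 0.6, emConfig = emc,
                                seed = 54)
  expect_identical(pairs[[1]]@input@data, pairs2[[1]]@input@data)
})

test_that("augmentation rotations are proper and centre-preserving", {
  rots <- cryored:::.cubeRotations()
  expect_length(rots, 24)
  a <- randomRealVolume(16, 1, seed = 55)@data
  for (rot in rots[c(1, 7, 19)]) {
    b <- cryored:::.applyCubeRotation(a, rot)
    expect_equal(sort(as.vector(b[2:16, 2:16, 2:16])),
                 sort(as.vector(a[2:16, 2:16, 2:16])))
    expect_equal(b[9, 9, 9], a[9, 9, 9])  # rotation centre fixed
  }
})

test_that("Gaussian-noise corpus matches its noise profile", {
  gt <- makePhantom(phantomSpec(side = 32, voxelSize = 3, seed = 56))
  ns <- 17
  ## zero noise: input equals the ground truth
  p0 <- buildGaussianNoiseCorpus(list(gt), rep(0, ns), seed = 57,
                                 perPhantom = 1)
  expect_equal(p0[[1]]@input@data, gt@data, tolerance = 1e-9)
  ## drawn noise matches the requested shell power within 3 SE
  prof <- seq(2, 0.5, length.out = ns)
  set.seed(58)
  nDraws <- 50
  pw <- matrix(0, nDraws, ns)
  for (i in seq_len(nDraws)) {
    noise <- cryored:::.hermitianGaussianNoise(32, prof)
    pw[i, ] <- shellValues(shellAverage(Mod(noise)^2))
  }
  voxPerShell <- tabulate(pmin(round(cryored:::.gridGeometry(32, 3L)$r),
                               16) + 1, ns)
  meanPw <- colMeans(pw)
  se <- prof * sqrt(2 / (voxPerShell * nDraws))
  expect_true(all(abs(meanPw[2:ns] - prof[2:ns]) < 3 * se[2:ns]))
  ## determinism
  pa <- buildGaussianNoiseCorpus(list(gt), prof, seed = 59, perPhantom = 2)
  pb <- buildGaussianNoiseCorpus(list(gt), prof, seed = 59, perPhantom = 2)
  expect_identical(pa[[2]]@input@data, pb[[2]]@input@data)
})

test_that("a short training run reduces the empirical risk", {
  gt <- makePhantom(phantomSpec(side = 32, voxelSize = 3, seed = 60))
  set.seed(61)
  pairs <- lapply(1:10, function(i) {
    noisy <- realVolume(gt@data + array(rnorm(32^3, sd = 0.4),
                                        dim(gt@data)), 3)
    new("TrainingPair", input = noisy, target = gt,
        nominalResolution = 12, phantomId = sprintf("p%d", i %% 3))
  })
  d <- trainDenoiser(pairs, spec = unetSpec(stages = 3, baseChannels = 2),
                     epochs = 2, lr = 1e-3, batch = 5, seed = 62,
                     validFrac = 0)
  tr <- attr(d, "lossTrace")
  expect_equal(nrow(tr), 2)
  expect_lt(tr$train[2], tr$train[1])
  ## the handle honours the standardization contract dimensions
  out <- standardizedDenoise(d, pairs[[1]]@input)
  expect_identical(dim(out@data), dim(gt@data))
})

test_that("training on a Gaussian toy approaches closed-form shrinkage", {
  ## prior N(0, r^2) per voxel, noise N(0, u): MMSE is linear shrinkage
  r2 <- 1; u <- 0.5
  cshr <- r2 / (r2 + u)
  set.seed(63)
  pairs <- lapply(1:12, function(i) {
    clean <- array(rnorm(16^3, sd = sqrt(r2)), c(16, 16, 16))
    noisy <- clean + array(rnorm(16^3, sd = sqrt(u)), c(16, 16, 16))
    new("TrainingPair", input = realVolume(noisy, 1),
        target = realVolume(clean, 1),
        nominalResolution = 10, phantomId = sprintf("p%d", i))
  })
  spec <- unetSpec(stages = 2, baseChannels = 2)
  devToShrinkage <- function(d) {
    mean(vapply(pairs[1:3], function(p) {
      got <- standardizedDenoise(d, p@input)@data
      want <- cshr * p@input@data
      mean((got - want)^2)
    }, numeric(1)))
  }
  d0 <- trainDenoiser(pairs, spec, epochs = 1, lr = 3e-3, batch = 4,
                      seed = 64, validFrac = 0)
  d1 <- trainDenoiser(pairs, spec, epochs = 6, lr = 3e-3, batch = 4,
                      seed = 64, validFrac = 0)
  ## more epochs move the learned map closer to the analytic estimator
  expect_lt(devToShrinkage(d1), devToShrinkage(d0))
})

test_that("the classical denoiser is a monotone shell filter", {
  cl0 <- classicalDenoiser(0)
  v <- randomRealVolume(16, 2, seed = 65)
  expect_identical(standardizedDenoise(cl0, v)@data, v@data)
  pw <- function(d) shellValues(shellAverage(
    Mod(forwardTransform(standardizedDenoise(d, v))@data)^2))
  p1 <- pw(classicalDenoiser(1)); p2 <- pw(classicalDenoiser(2.5))
  expect_true(all(p2[3:9] <= p1[3:9] + 1e-12))
  ## some strength improves a noisy phantom
  gt <- makePhantom(phantomSpec(side = 16, voxelSize = 3, seed = 66))
  set.seed(67)
  noisy <- realVolume(gt@data + array(rnorm(16^3, sd = 0.5), dim(gt@data)),
                      3)
  base <- sqrt(sum((noisy@data - gt@data)^2))
  improved <- vapply(c(0.5, 1, 1.5, 2), function(s) {
    den <- standardizedDenoise(classicalDenoiser(s), noisy)
    sqrt(sum((den@data - gt@data)^2))
  }, numeric(1))
  expect_lt(min(improved), base)
})

test_that("corpus noise profiles are measured from residuals", {
  gt <- makePhantom(phantomSpec(side = 16, voxelSize = 3, seed = 68))
  set.seed(69)
  pairs <- lapply(1:6, function(i) {
    noisy <- realVolume(gt@data + array(rnorm(16^3, sd = 0.3),
                                        dim(gt@data)), 3)
    new("TrainingPair", input = noisy, target = gt,
        nominalResolution = 12, phantomId = "p1")
  })
  prof <- corpusNoiseProfile(pairs)
  ## white residual noise of variance 0.09 has flat shell power 0.09
  expect_equal(mean(shellValues(prof)[2:9]), 0.09, tolerance = 0.03)
})
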