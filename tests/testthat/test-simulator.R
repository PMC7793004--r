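test_that("phantoms are deterministic and confined to the support sphere", {
  spec <- phantomSpec(side = 32, voxelSize = 3, seed = 42)
  p1 <- makePhantom(spec)
  p2 <- makePhantom(spec)
  expect_identical(p1@data, p2@data)
  expect_true(all(p1@data >= 0))
  k <- seq_len(32) - 1 - 16
  r <- sqrt(outer(outer(k^2, k^2, `+`), k^2, `+`))
  expect_true(all(p1@data[r >= 0.45 * 32] == 0))
})

test_that("a single blob has the analytic Gaussian integral", {
  spec <- phantomSpec(side = 32, voxelSize = 3, nBlobs = 1,
                      blobSigmaRange = c(4.5, 4.5), seed = 3)
  p <- makePhantom(spec)
  sigmaVox <- 4.5 / 3
  expect_equal(sum(p@data), (2 * pi)^(3 / 2) * sigmaVox^3,
               tolerance = 0.01)
})

test_that("elongation increases the principal moment anisotropy", {
  iso <- makePhantom(phantomSpec(side = 32, voxelSize = 3, elongation = 1,
                                 seed = 5))
  elo <- makePhantom(phantomSpec(side = 32, voxelSize = 3, elongation = 3,
                                 seed = 5))
  expect_gt(momentAnisotropy(elo), momentAnisotropy(iso))
})

test_that("datasets are pure functions of their seed", {
  gt <- makePhantom(phantomSpec(side = 16, voxelSize = 3, seed = 1))
  d1 <- simulateDataset(gt, 5, intensityScale = 0.1, seed = 9)
  d2 <- simulateDataset(gt, 5, intensityScale = 0.1, seed = 9)
  expect_identical(d1@images, d2@images)
  expect_identical(lapply(d1@poses, function(p) p@rotation),
                   lapply(d2@poses, function(p) p@rotation))
})

test_that("SNR follows the quadratic scaling law and edge cases", {
  gt <- makePhantom(phantomSpec(side = 16, voxelSize = 3, seed = 2))
  d1 <- simulateDataset(gt, 20, intensityScale = 0.1, seed = 4)
  d2 <- simulateDataset(gt, 20, intensityScale = 0.2, seed = 4)
  expect_equal(d2@snr / d1@snr, 4, tolerance = 1e-12)
  d0 <- simulateDataset(gt, 5, intensityScale = 0, seed = 4)
  expect_equal(d0@snr, 0)
})

test_that("computeSnr implements the per-pixel variance definition", {
  expect_equal(computeSnr(list(matrix(0, 8, 8)), 1), 0)
  expect_equal(computeSnr(list(matrix(7, 8, 8)), 1), 0)  # flat image
  set.seed(6)
  imgs <- list(matrix(rnorm(64), 8), matrix(rnorm(64), 8))
  v <- mean(vapply(imgs, function(im) mean((im - mean(im))^2), numeric(1)))
  expect_equal(computeSnr(imgs, 2), v / 2)
  expect_error(computeSnr(imgs, 0), "noiseVariance")
})

test_that("added noise has the stated unity variance", {
  gt <- makePhantom(phantomSpec(side = 32, voxelSize = 3, seed = 7))
  noisy <- simulateDataset(gt, 60, intensityScale = 0.3, noiseSd = 1,
                           seed = 13)
  clean <- simulateDataset(gt, 60, intensityScale = 0.3, noiseSd = 0,
                           seed = 13)
  nz <- datasetRealImages(noisy) - datasetRealImages(clean)
  nPix <- length(nz)
  se <- sqrt(2 / nPix)
  expect_lt(abs(var(as.vector(nz)) - 1), 3 * se)
  ## the recorded frequency-space noise power matches the measurement
  pw <- mean(Mod(noisy@images - clean@images)^2)
  expect_equal(pw, 1, tolerance = 3 * se)
  expect_equal(shellValues(noisy@sigma2)[1], 1)
})

test_that("known-pose reconstruction of noiseless data recovers the map", {
  gt <- makePhantom(phantomSpec(side = 32, voxelSize = 3, seed = 8))
  ds <- simulateDataset(gt, 400, intensityScale = 1, noiseSd = 0, seed = 3)
  grid <- poseGridFromPoses(ds@poses)
  model0 <- forwardTransform(lowpassVolume(gt, 30))
  es <- estep(ds, model0, grid)
  x <- es$acc@B / es$acc@K
  x[!is.finite(x)] <- 0i
  fr <- fsc(fourierVolume(x, 3), forwardTransform(gt))
  upTo <- floor(0.8 * 16)
  expect_true(all(shellValues(fr)[seq_len(upTo + 1)] > 0.95))
})
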