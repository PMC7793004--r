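## Shared fixtures: all built in code, deterministic under explicit seeds.

randomRealVolume <- function(n = 16, voxel = 2, seed = 1) {
  set.seed(seed)
  realVolume(array(rnorm(n^3), c(n, n, n)), voxel)
}

randomFourierVolume <- function(n = 16, voxel = 2, seed = 1) {
  forwardTransform(randomRealVolume(n, voxel, seed))
}

## A centred Gaussian blob whose discrete transform pair is closed-form to
## machine precision (both tails are far below 1e-8 at these settings).
gaussianBlobVolume <- function(n = 32, sigma = 2, voxel = 1) {
  k <- seq_len(n) - 1 - n / 2
  d2 <- outer(outer(k^2, k^2, `+`), k^2, `+`)
  realVolume(array(exp(-d2 / (2 * sigma^2)), c(n, n, n)), voxel)
}

gaussianBlobSpectrum <- function(n = 32, sigma = 2, voxel = 1) {
  k <- seq_len(n) - 1 - n / 2
  d2 <- outer(outer(k^2, k^2, `+`), k^2, `+`)
  amp <- (2 * pi * sigma^2)^(3 / 2) / n^(3 / 2)
  fourierVolume(array(amp * exp(-2 * pi^2 * sigma^2 * d2 / n^2) + 0i,
                      c(n, n, n)), voxel)
}

## The 24 proper signed-permutation rotation matrices (on-lattice poses:
## trilinear interpolation is exact for these).
latticeRotations <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  out <- list()
  for (p in perms) {
    P <- diag(3)[p, ]
    for (sx in c(1, -1)) for (sy in c(1, -1)) for (sz in c(1, -1)) {
      R <- diag(c(sx, sy, sz)) %*% P
      if (abs(det(R) - 1) < 1e-12) out[[length(out) + 1L]] <- R
    }
  }
  out
}

## Build a SimulatedDataset from explicit poses (toy problems).
makeToyDataset <- function(gt, poses, noiseSd = 0.5, seed = 1,
                           intensityScale = 1) {
  set.seed(seed)
  n <- gridSide(gt)
  fgt <- forwardTransform(realVolume(gt@data * intensityScale,
                                     gt@voxelSize))
  m <- length(poses)
  images <- array(0i, c(n, n, m))
  for (i in seq_len(m)) {
    clean <- .inverseTransform2Test(project(fgt, poses[[i]]))
    noisy <- clean + if (noiseSd > 0)
      matrix(rnorm(n * n, sd = noiseSd), n, n) else 0
    images[, , i] <- .forwardTransform2Test(noisy)
  }
  sig2 <- if (noiseSd > 0) noiseSd^2 else 1
  new("SimulatedDataset", images = images, poses = poses,
      meta = data.frame(defocus = rep(NA_real_, m)),
      groundTruth = gt,
      sigma2 = shellProfile(rep(sig2, n %/% 2 + 1), "sigma2"),
      intensityScale = intensityScale, snr = 0, noiseSd = noiseSd)
}

## Unitary centred 2D transforms (test-side copies of the conventions).
.forwardTransform2Test <- function(img) {
  n <- dim(img)[1]
  sh <- function(a) {
    i <- c((n / 2 + 1):n, 1:(n / 2))
    a[i, i]
  }
  sh(fft(sh(img + 0i))) / n
}

.inverseTransform2Test <- function(f) {
  n <- dim(f)[1]
  sh <- function(a) {
    i <- c((n / 2 + 1):n, 1:(n / 2))
    a[i, i]
  }
  Re(sh(fft(sh(f), inverse = TRUE))) / n
}

## Random accumulator with strictly positive K and Hermitian B.
randomAccumulator <- function(n = 16, voxel = 2, seed = 1) {
  set.seed(seed)
  b <- forwardTransform(realVolume(array(rnorm(n^3), c(n, n, n)),
                                   voxel))@data
  k <- array(runif(n^3, 0.5, 2), c(n, n, n))
  k <- (k + k[c(1, n:2), c(1, n:2), c(1, n:2)]) / 2  # Friedel-symmetric
  new("AccumulatorPair", B = b, K = k, voxelSize = voxel)
}
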