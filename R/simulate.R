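## Synthetic projection data sets: uniform SO(3) poses, optional defocus-
## varying CTF, and white real-space Gaussian noise of known variance.
##
## Because the transforms are unitary, real-space white noise of variance
## noiseSd^2 per pixel has frequency-space power exactly noiseSd^2 per
## complex coefficient; the recorded sigma2 profile is that constant (the
## normalization factor is 1 by construction, and tests verify the
## measured shell power agrees).

#' Simulate a projection data set from a ground-truth volume
#'
#' The ground truth is scaled by `intensityScale`, projected at poses drawn
#' uniformly on SO(3) (translations uniform in +/- `translationMax`
#' pixels), multiplied by a CTF with defocus drawn uniformly in `ctfRange`
#' (when given), and white Gaussian noise of standard deviation `noiseSd`
#' is added per real-space pixel.
#'
#' @param gt a [RealVolume-class] ground truth.
#' @param nImages number of images (>= 1).
#' @param intensityScale positive scale applied to the ground truth; 0 is
#'   allowed and yields pure-noise images with SNR 0.
#' @param ctfRange NULL to disable the CTF, else c(min, max) defocus in
#'   micrometre.
#' @param translationMax maximum in-plane shift in pixels (uniform draw).
#' @param noiseSd real-space noise standard deviation (1 reproduces the
#'   unity-variance contract; 0 gives noiseless data, in which case the
#'   recorded sigma2 falls back to 1 so likelihood weights stay defined).
#' @param seed integer seed; the data set is a pure function of the inputs.
#' @return A [SimulatedDataset-class].
#' @export
simulateDataset <- function(gt, nImages, intensityScale = 1,
                            ctfRange = NULL, translationMax = 0,
                            noiseSd = 1, seed = 1) {
  stopifnot(is(gt, "RealVolume"), nImages >= 1)
  if (intensityScale < 0) stop("intensityScale must be nonnegative")
  set.seed(seed)
  n <- gridSide(gt)
  fgt <- forwardTransform(realVolume(gt@data * intensityScale, gt@voxelSize))
  useCtf <- !is.null(ctfRange)
  ## all pose/CTF draws happen before any noise draw, so re-simulating with
  ## the same seed and noiseSd = 0 yields the matched clean images and the
  ## noise component is exactly (noisy - clean)
  poses <- lapply(seq_len(nImages), function(i) {
    R <- quaternionToMatrix(rnorm(4))
    tr <- if (translationMax > 0)
      runif(2, -translationMax, translationMax) else c(0, 0)
    pose(R, tr)
  })
  defocus <- if (useCtf) runif(nImages, ctfRange[1], ctfRange[2]) else
    rep(NA_real_, nImages)
  images <- array(0i, c(n, n, nImages))
  cleanVar <- numeric(nImages)
  for (i in seq_len(nImages)) {
    ctf <- if (useCtf) ctfParams(defocus = defocus[i]) else
      ctfParams(enabled = FALSE)
    yClean <- project(fgt, poses[[i]], ctf)
    cleanReal <- .inverseTransform2(yClean)
    cleanVar[i] <- mean((cleanReal - mean(cleanReal))^2)
    noisy <- cleanReal + if (noiseSd > 0)
      matrix(rnorm(n * n, sd = noiseSd), n, n) else 0
    images[, , i] <- .forwardTransform2(noisy)
  }
  sig2 <- if (noiseSd > 0) noiseSd^2 else 1
  snr <- if (noiseSd > 0) mean(cleanVar) / noiseSd^2 else 0
  new("SimulatedDataset", images = images, poses = poses,
      meta = data.frame(defocus = defocus),
      groundTruth = gt,
      sigma2 = shellProfile(rep(sig2, n %/% 2 + 1L), "sigma2"),
      intensityScale = intensityScale, snr = snr, noiseSd = noiseSd)
}

#' Signal-to-noise ratio of clean projections
#'
#' Mean over images of the per-image pixel variance of the clean (noise
#' free) projection, divided by the noise variance.
#'
#' @param cleanImages list (or N x N x m array) of real-space clean images.
#' @param noiseVariance positive noise variance.
#' @return numeric SNR.
#' @export
computeSnr <- function(cleanImages, noiseVariance) {
  if (noiseVariance <= 0) stop("noiseVariance must be positive")
  if (is.array(cleanImages) && length(dim(cleanImages)) == 3L)
    cleanImages <- lapply(seq_len(dim(cleanImages)[3]),
                          function(i) cleanImages[, , i])
  if (!length(cleanImages)) stop("need at least one image")
  v <- vapply(cleanImages, function(im) mean((im - mean(im))^2), numeric(1))
  mean(v) / noiseVariance
}

#' Extract the per-image CTF parameter objects of a dataset
#' @param ds a [SimulatedDataset-class].
#' @return list of [CTFParams-class], one per image.
#' @export
datasetCtfs <- function(ds) {
  lapply(seq_len(imageCount(ds)), function(i) {
    dz <- ds@meta$defocus[i]
    if (is.na(dz)) ctfParams(enabled = FALSE) else ctfParams(defocus = dz)
  })
}

#' Subset a dataset by image index
#' @param ds a [SimulatedDataset-class].
#' @param idx integer image indices to keep.
#' @return A [SimulatedDataset-class] with the selected images.
#' @export
datasetSubset <- function(ds, idx) {
  new("SimulatedDataset",
      images = ds@images[, , idx, drop = FALSE],
      poses = ds@poses[idx],
      meta = ds@meta[idx, , drop = FALSE],
      groundTruth = ds@groundTruth, sigma2 = ds@sigma2,
      intensityScale = ds@intensityScale, snr = ds@snr,
      noiseSd = ds@noiseSd)
}

#' Real-space image stack of a dataset
#' @param ds a [SimulatedDataset-class].
#' @return N x N x m real array (inverse transforms of the stored images).
#' @export
datasetRealImages <- function(ds) {
  d <- dim(ds@images)
  out <- array(0, d)
  for (i in seq_len(d[3])) out[, , i] <- .inverseTransform2(ds@images[, , i])
  out
}
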