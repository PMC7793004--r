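## Denoiser training: building supervised pairs from refinement
## intermediates (or from pure Gaussian-noise corruption) and minimizing
## the empirical MMSE risk with Adam.

#' Coarsen a ground truth to match a noisy map's resolution
#'
#' Low-pass filters the ground truth by multiplying its Fourier transform
#' with the (half-map) FSC of the noisy input map, shell by shell.
#'
#' @param gt a [RealVolume-class] ground truth.
#' @param fscOfInput a [ShellProfile-class] (or numeric vector) of length
#'   N/2 + 1.
#' @return The coarsened [RealVolume-class].
#' @export
coarsenGroundTruth <- function(gt, fscOfInput) {
  inverseTransform(applyShellFilter(forwardTransform(gt), fscOfInput))
}

## The 24 proper rotations of the cube as axis permutation/sign pairs,
## applied to a 3D array without interpolation.
.cubeRotations <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  out <- list()
  for (p in perms) {
    inv <- sum(outer(seq_len(3), seq_len(3), function(i, j)
      i < j & p[i] > p[j]))
    parity <- if (inv %% 2 == 0) 1 else -1
    for (sx in c(1, -1)) for (sy in c(1, -1)) for (sz in c(1, -1)) {
      if (sx * sy * sz * parity == 1)
        out[[length(out) + 1L]] <- list(perm = p, flip = c(sx, sy, sz))
    }
  }
  out
}

## Apply a cube rotation to a centred even grid.  Flips are realized as
## index reversal followed by a one-voxel roll so the centre voxel (0-based
## N/2) stays fixed.
.applyCubeRotation <- function(a, rot) {
  n <- dim(a)[1]
  i <- seq_len(n)
  ## centre-fixed reversal: index 1 (the unpaired -N/2 plane) stays put,
  ## i -> n + 2 - i otherwise, so the rotation centre n/2 + 1 is fixed.
  idx <- lapply(1:3, function(ax) {
    if (rot$flip[ax] == 1) i else c(1L, rev(i[-1]))
  })
  aperm(a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE], rot$perm)
}

#' Build a training corpus from refinement intermediates
#'
#' For each phantom and SNR tier: simulate a projection data set, run a
#' Gaussian-prior half-set refinement keeping intermediates, and pair each
#' unregularized intermediate half-map with the ground truth coarsened by
#' that iteration's half-map FSC.  Optional augmentation replicates each
#' pair under proper 90-degree cube rotations.  Deterministic given
#' `seed`.
#'
#' @param phantomSpecs list of [phantomSpec()] objects.
#' @param snrTiers numeric vector of intensity scales (one data set per
#'   phantom x tier).
#' @param emConfig list of overrides: `nImages`, `grid`, `maxIterations`,
#'   `noiseSd`, `initialResolution`.
#' @param seed integer master seed.
#' @param augment number of cube rotations per pair (1 = no augmentation,
#'   up to 24).
#' @return list of [TrainingPair-class]; phantoms whose refinement
#'   diverges are skipped with a warning.
#' @export
buildTrainingCorpus <- function(phantomSpecs, snrTiers, emConfig = list(),
                                seed = 1, augment = 1) {
  cfg <- modifyList(list(nImages = 300, grid = NULL, maxIterations = 6,
                         noiseSd = 1, initialResolution = 30), emConfig)
  rots <- .cubeRotations()[seq_len(max(1, min(augment, 24)))]
  pairs <- list()
  job <- 0L
  for (ip in seq_along(phantomSpecs)) {
    ph <- makePhantom(phantomSpecs[[ip]])
    pid <- sprintf("phantom%02d", ip)
    for (tier in snrTiers) {
      job <- job + 1L
      ds <- simulateDataset(ph, cfg$nImages, intensityScale = tier,
                            noiseSd = cfg$noiseSd,
                            seed = .subSeed(seed, job))
      run <- tryCatch(
        runRefinement(ds, refinementConfig(
          regularizer = "gaussian", grid = cfg$grid,
          maxIterations = cfg$maxIterations,
          initialResolution = cfg$initialResolution,
          keepIntermediates = TRUE)),
        error = function(e) {
          warning(sprintf("refinement failed for %s tier %.4g: %s",
                          pid, tier, conditionMessage(e)))
          NULL
        })
      if (is.null(run)) next
      gtScaled <- realVolume(ph@data * tier, ph@voxelSize)
      for (rec in run$intermediates) {
        target <- coarsenGroundTruth(gtScaled,
                                     pmax(0, rec$fscHalf@values))
        for (rot in rots) {
          pairs[[length(pairs) + 1L]] <- new("TrainingPair",
            input = realVolume(.applyCubeRotation(rec$xtilde@data, rot),
                               ph@voxelSize),
            target = realVolume(.applyCubeRotation(target@data, rot),
                                ph@voxelSize),
            nominalResolution = rec$nominalResolution,
            phantomId = pid)
        }
      }
    }
  }
  pairs
}

#' Build a Gaussian-noise training corpus
#'
#' The noise-model variant: for each phantom, Hermitian Gaussian noise is
#' drawn in frequency space with per-shell power matching `noiseProfile`,
#' transformed to real space, dampened in the solvent region by a soft
#' spherical mask, and added to the ground truth.  Targets are the ground
#' truth coarsened by the measured FSC between the corrupted map and the
#' truth.
#'
#' @param phantoms list of [RealVolume-class] ground truths (or
#'   [phantomSpec()]s, realized internally).
#' @param noiseProfile a [ShellProfile-class] (kind sigma2/power) of
#'   per-shell noise power.
#' @param solventMaskParams list(radiusFrac, edgeVoxels) of the soft mask.
#' @param seed integer seed.
#' @param perPhantom number of noise draws per phantom.
#' @return list of [TrainingPair-class].
#' @export
buildGaussianNoiseCorpus <- function(phantoms, noiseProfile,
                                     solventMaskParams = list(
                                       radiusFrac = 0.4, edgeVoxels = 5),
                                     seed = 1, perPhantom = 4) {
  prof <- if (is(noiseProfile, "ShellProfile")) noiseProfile@values
          else as.numeric(noiseProfile)
  if (any(prof < 0)) stop("noise profile must be nonnegative")
  pairs <- list()
  job <- 0L
  for (ip in seq_along(phantoms)) {
    ph <- phantoms[[ip]]
    if (inherits(ph, "PhantomSpec")) ph <- makePhantom(ph)
    n <- gridSide(ph)
    vx <- ph@voxelSize
    radius <- solventMaskParams$radiusFrac * n * vx
    edge <- min(solventMaskParams$edgeVoxels * vx, n * vx / 2 - radius)
    mask <- softMask(n, vx, radius = radius, edgeWidth = edge)
    pid <- sprintf("phantom%02d", ip)
    for (rep in seq_len(perPhantom)) {
      job <- job + 1L
      set.seed(.subSeed(seed, job))
      noise <- .hermitianGaussianNoise(n, prof)
      noiseReal <- inverseTransform(fourierVolume(noise, vx), tol = Inf)
      noisy <- realVolume(ph@data + noiseReal@data * mask@data, vx)
      f <- pmax(0, fsc(noisy, ph)@values)
      pairs[[length(pairs) + 1L]] <- new("TrainingPair",
        input = noisy, target = coarsenGroundTruth(ph, f),
        nominalResolution = resolutionAt(shellProfile(pmin(1, f), "fsc"),
                                         0.143, vx),
        phantomId = pid)
    }
  }
  pairs
}

## Hermitian complex Gaussian field with per-shell power prof[s+1]:
## real white noise shaped per shell has exactly Hermitian symmetry and
## E|F(k)|^2 = prof at the shell of k.
.hermitianGaussianNoise <- function(n, prof) {
  w <- array(rnorm(n^3), c(n, n, n))
  f <- .unitaryFFT(w + 0i)
  f * .shellFactorGrid(sqrt(prof), n)
}

#' Measure the residual noise shell power of a corpus
#'
#' The per-shell power of (input - target) averaged over pairs: the
#' estimator behind the Gaussian-noise training variant's noise profile.
#'
#' @param pairs list of [TrainingPair-class].
#' @return A [ShellProfile-class] of kind `"sigma2"`.
#' @export
corpusNoiseProfile <- function(pairs) {
  acc <- NULL
  for (p in pairs) {
    d <- forwardTransform(realVolume(p@input@data - p@target@data,
                                     p@input@voxelSize))
    pw <- .shellMean(Mod(d@data)^2)
    acc <- if (is.null(acc)) pw else acc + pw
  }
  shellProfile(pmax(acc / length(pairs), 1e-12), "sigma2")
}

#' Train the volumetric residual U-Net denoiser
#'
#' Minimizes the empirical mean squared error between the network output
#' and the coarsened ground truth on standardized volumes (both input and
#' target standardized by the input's mean and standard deviation, so the
#' standardization reversal of [standardizedDenoise()] maps predictions
#' back to map units).  L2 weight regularization via Adam; residual
#' parameterization, so the untrained network is the identity.
#'
#' @param pairs list of [TrainingPair-class].
#' @param spec a [unetSpec()].
#' @param epochs training epochs.
#' @param lr Adam learning rate.
#' @param batch mini-batch size.
#' @param weightDecay L2 penalty on weights.
#' @param seed integer seed (initialization and shuffling).
#' @param validFrac fraction of phantoms held out for validation loss
#'   reporting (split by phantom identity, never by iteration).
#' @param trainedOn provenance tag recorded on the returned handle
#'   (`"refinement_intermediates"` or `"gaussian_noise"`).
#' @param verbose print per-epoch losses.
#' @return A [DenoiserHandle-class] with attributes `weights`, `spec` and
#'   `lossTrace` (data.frame epoch/train/valid).
#' @export
trainDenoiser <- function(pairs, spec = unetSpec(), epochs = 4, lr = 1e-3,
                          batch = 4, weightDecay = 1e-6, seed = 1,
                          validFrac = 0.1, verbose = FALSE,
                          trainedOn = "refinement_intermediates") {
  stopifnot(length(pairs) >= 1)
  n <- gridSide(pairs[[1]]@input)
  if (n %% 2^spec$stages != 0)
    stop(sprintf("volume side %d not divisible by 2^%d stages", n,
                 spec$stages))
  std <- lapply(pairs, function(p) {
    mu <- mean(p@input@data); s <- sd(as.vector(p@input@data))
    if (s == 0) stop("zero-variance training input")
    list(zin = (p@input@data - mu) / s, ztgt = (p@target@data - mu) / s,
         phantomId = p@phantomId)
  })
  pids <- unique(vapply(std, `[[`, character(1), "phantomId"))
  set.seed(.subSeed(seed, 0))
  nValid <- floor(length(pids) * validFrac)
  validPids <- if (nValid > 0) sample(pids, nValid) else character(0)
  isValid <- vapply(std, function(s) s$phantomId %in% validPids, logical(1))
  trainSet <- std[!isValid]; validSet <- std[isValid]
  if (!length(trainSet)) { trainSet <- std; validSet <- list() }

  params <- unetInit(spec, seed = .subSeed(seed, 1))
  state <- adamInit(params)
  mse <- function(set) {
    if (!length(set)) return(NA_real_)
    mean(vapply(set, function(s) {
      out <- unetForward(s$zin, params, spec)$out
      mean((out - s$ztgt)^2)
    }, numeric(1)))
  }
  trace <- data.frame(epoch = integer(0), train = numeric(0),
                      valid = numeric(0))
  for (ep in seq_len(epochs)) {
    set.seed(.subSeed(seed, 100 + ep))
    ord <- sample(length(trainSet))
    epochLoss <- 0
    nb <- 0L
    for (start in seq(1, length(ord), by = batch)) {
      ids <- ord[start:min(start + batch - 1L, length(ord))]
      grads <- NULL
      bl <- 0
      for (id in ids) {
        s <- trainSet[[id]]
        fw <- unetForward(s$zin, params, spec, wantCache = TRUE)
        resid <- fw$out - s$ztgt
        bl <- bl + mean(resid^2)
        dOut <- 2 * resid / length(resid)
        g <- unetBackward(fw$cache, dOut, params, spec)
        grads <- if (is.null(grads)) g else .paramWalk(grads, g, `+`)
      }
      grads <- .paramWalk(grads, grads, function(a, b) a / length(ids))
      r <- adamStep(params, grads, state, lr = lr,
                    weightDecay = weightDecay)
      params <- r$params; state <- r$state
      epochLoss <- epochLoss + bl / length(ids)
      nb <- nb + 1L
    }
    trace <- rbind(trace, data.frame(epoch = ep, train = epochLoss / nb,
                                     valid = mse(validSet)))
    if (verbose)
      message(sprintf("epoch %d: train %.5f valid %.5f", ep,
                      trace$train[ep], trace$valid[ep]))
  }
  d <- .unetHandle(params, spec, sprintf("unet-s%d-c%d", spec$stages,
                                         spec$baseChannels), trainedOn)
  attr(d, "lossTrace") <- trace
  d
}
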