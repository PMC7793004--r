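## Marginalized MAP-EM core.
##
## E-step: per image i and pose g the log-weight is
##   log gamma*_ig = log pi(g) - sum_k |y_ik - (H_g x)_k|^2 / (2 sigma2_k),
## normalized per image by logsumexp (all arithmetic in the log domain;
## SNRs of order 1e-3 underflow linear-domain weights).  The quadratic
## expands into an image self-term, a cross term and a slice power term, so
## the whole E-step reduces to two dense matrix products against the
## pre-projected pose slices.
##
## Accumulation: B = sum_ig gamma_ig H_g* (y_i / sigma2), and K collects
## gamma_ig CTF^2 / sigma2 with the same interpolation weights; off-
## diagonal components of H*H are discarded (K is stored diagonal).

#' E-step: responsibilities and accumulators
#'
#' @param ds a [SimulatedDataset-class] (any object with images, CTFs and a
#'   sigma2 profile produced by the simulator or [datasetSubset()]).
#' @param model a [FourierVolume-class], the current reference.
#' @param grid a [PoseGrid-class].
#' @param sigma2 optional [ShellProfile-class] overriding the dataset's
#'   per-shell noise power.
#' @return A list with `gamma` (images x poses responsibilities, rows sum
#'   to 1), `acc` (an [AccumulatorPair-class]), `logLik` (per-image
#'   marginal log-likelihood up to the sigma-normalization constant),
#'   `bestPose` (per-image argmax responsibility index).
#' @export
estep <- function(ds, model, grid, sigma2 = NULL) {
  stopifnot(is(model, "FourierVolume"), is(grid, "PoseGrid"))
  n <- gridSide(model)
  if (dim(ds@images)[1] != n) stop("model side does not match images")
  if (is.null(sigma2)) sigma2 <- ds@sigma2
  m <- imageCount(ds)
  nP <- poseCount(grid)
  npix <- n * n
  wpix <- 1 / .shellFactorImage(sigma2@values, n)  # 1/sigma^2 per pixel
  wpix <- as.vector(wpix)

  ## image matrix (m x npix) and per-image CTF
  Y <- t(matrix(ds@images, npix, m))
  ctfs <- datasetCtfs(ds)
  ctfOn <- any(vapply(ctfs, function(c) c@enabled, logical(1)))
  C <- if (ctfOn) {
    do.call(rbind, lapply(ctfs, .ctfImage, n = n, voxel = model@voxelSize))
  } else matrix(1, m, npix)

  ## pose slices including the translation phase ramp (nP x npix)
  P <- matrix(0i, nP, npix)
  for (g in seq_len(nP)) {
    P[g, ] <- .extractSlice(model@data, grid@rotations[[g]]) *
      .translationPhase(grid@translations[g, ], n)
  }

  Ytil <- Y * C * rep(wpix, each = m)       # w c y
  Cw2 <- C * C * rep(wpix, each = m)        # w c^2
  cross <- Re(Ytil %*% Conj(t(P)))
  quad <- 0.5 * (Cw2 %*% t(Mod(P)^2))
  selfTerm <- 0.5 * as.vector((Mod(Y)^2) %*% wpix)
  logW <- sweep(cross - quad, 2, grid@logPrior, `+`)

  if (anyNA(logW))
    stop("estep: NaN in log-weights (numerical failure)")
  lse <- .rowLogSumExp(logW)
  if (any(!is.finite(lse)))
    stop("estep: numerical underflow, all pose weights vanished for an image")
  gamma <- exp(logW - lse)

  ## aggregate images per pose, then one adjoint insertion per pose
  BW <- t(gamma) %*% Ytil                   # nP x npix complex
  KW <- t(gamma) %*% Cw2                    # nP x npix real
  Bacc <- array(0i, c(n, n, n))
  Kacc <- array(0, c(n, n, n))
  for (g in seq_len(nP)) {
    ph <- Conj(.translationPhase(grid@translations[g, ], n))
    upd <- .scatterSlice(BW[g, ] * ph, KW[g, ], grid@rotations[[g]],
                         Bacc, Kacc)
    Bacc <- upd$B; Kacc <- upd$K
  }
  Bacc <- .hermitianize(Bacc)
  Kacc <- .symmetrizeReal(Kacc)
  acc <- new("AccumulatorPair", B = Bacc, K = pmax(Kacc, 0),
             voxelSize = model@voxelSize)
  list(gamma = gamma, acc = acc, logLik = lse - selfTerm,
       bestPose = max.col(gamma, ties.method = "first"))
}

## Friedel-symmetrize a real kernel grid (matches .hermitianize).
.symmetrizeReal <- function(a) {
  n <- dim(a)[1]
  ix <- 2:n
  g <- a[ix, ix, ix, drop = FALSE]
  a[ix, ix, ix] <- (g + a[rev(ix), rev(ix), rev(ix), drop = FALSE]) / 2
  a
}

#' Gaussian-prior (Wiener) M-step
#'
#' Closed-form maximizer of the regularized quadratic: per Fourier voxel
#' `x = B / (K + tau^-2)` with the inverse signal power evaluated at the
#' voxel's shell.  Shells with `tau2 = 0` mean infinite regularization and
#' shrink fully to the prior mean (0); voxels where `K + tau^-2 = 0` are 0.
#'
#' @param acc an [AccumulatorPair-class].
#' @param tau2 a [ShellProfile-class] of per-shell signal power.
#' @return A [FourierVolume-class].
#' @export
mstepGaussian <- function(acc, tau2) {
  stopifnot(is(acc, "AccumulatorPair"))
  tinv <- .tauInvGrid(tau2, dim(acc@B)[1])
  x <- acc@B / (acc@K + tinv)
  x[!is.finite(x)] <- 0i    # tau2 = 0 shells and K + tinv = 0 voxels
  fourierVolume(x, acc@voxelSize)
}

## Per-voxel tau^-2 grid; Inf where tau2 = 0 (full shrinkage).
.tauInvGrid <- function(tau2, n) {
  vals <- if (is(tau2, "ShellProfile")) tau2@values else as.numeric(tau2)
  if (length(vals) != n %/% 2 + 1L) stop("tau2 length does not match grid")
  tinv <- ifelse(vals > 0, 1 / vals, Inf)
  .shellFactorGrid(tinv, n)
}

#' Estimate per-shell signal power from two half-maps
#'
#' Empirical-Bayes estimate driven by the half-map FSC: per shell,
#' `tau2 = FSC/(1 - FSC) * P` with the FSC clamped to \[0, 0.999\] and P
#' the radial mean power of the average of the two half-maps.  FSC <= 0
#' yields tau2 = 0 (infinite regularization toward the prior mean); the
#' clamp keeps the signal power finite when the halves agree perfectly.
#'
#' @param half1,half2 [FourierVolume-class] half-set models.
#' @param fscOverride optional [ShellProfile-class]/numeric replacing the
#'   measured FSC (used to seed the first iteration from a low-pass
#'   reference whose halves are identical).
#' @return A [ShellProfile-class] of kind `"tau2"`.
#' @export
estimateTau2 <- function(half1, half2, fscOverride = NULL) {
  f <- if (is.null(fscOverride)) fsc(half1, half2)@values
       else if (is(fscOverride, "ShellProfile")) fscOverride@values
       else as.numeric(fscOverride)
  f <- pmin(0.999, pmax(0, f))
  avg <- (half1@data + half2@data) / 2
  pw <- .shellMean(Mod(avg)^2)
  shellProfile(ifelse(f <= 0, 0, f / (1 - f) * pw), "tau2")
}

#' Marginal log-posterior of a model (Gaussian prior)
#'
#' The EM objective: sum over images of the pose-marginalized Gaussian
#' log-likelihood (up to the sigma-normalization constant) plus the
#' Gaussian log-prior `-sum_k |x_k|^2 / (2 tau2)`.  Used to verify the
#' ascent property of the EM iteration on toy problems.
#'
#' @param ds dataset, @param model reference, @param grid pose grid,
#'   @param tau2 fixed per-shell signal power.
#' @return numeric scalar.
#' @export
emObjective <- function(ds, model, grid, tau2) {
  es <- estep(ds, model, grid)
  tinv <- .tauInvGrid(tau2, gridSide(model))
  pri <- -0.5 * sum((Mod(model@data)^2 * tinv)[is.finite(tinv)])
  if (any(Mod(model@data)[!is.finite(tinv)] > 0)) pri <- -Inf
  sum(es$logLik) + pri
}

#' One EM iteration with fixed regularization
#'
#' @inheritParams emObjective
#' @return The updated [FourierVolume-class].
#' @export
emIterate <- function(ds, model, grid, tau2) {
  es <- estep(ds, model, grid)
  mstepGaussian(es$acc, tau2)
}

#' Refinement configuration
#'
#' @param regularizer one of `"gaussian"`, `"red"`, `"cwred"`.
#' @param grid a [PoseGrid-class]; NULL selects the default global grid.
#' @param maxIterations iteration cap.
#' @param patience stop after this many iterations without nominal-
#'   resolution improvement (default: never stop early).
#' @param denoiser a [DenoiserHandle-class] (required for red/cwred).
#' @param lambdaFixed fixed confidence weight for `"red"` (default 1).
#' @param schedule a [LambdaSchedule-class] for `"cwred"`.
#' @param initialResolution low-pass cutoff (Angstrom) of the starting
#'   reference (the ground-truth map filtered to 30 Angstrom by default).
#' @param keepIntermediates record unregularized half-maps per iteration.
#' @param verbose print per-iteration progress.
#' @return A list of class `"RefinementConfig"`.
#' @export
refinementConfig <- function(regularizer = c("gaussian", "red", "cwred"),
                             grid = NULL, maxIterations = 10,
                             patience = maxIterations, denoiser = NULL,
                             lambdaFixed = NULL,
                             schedule = lambdaSchedule(),
                             initialResolution = 30,
                             keepIntermediates = FALSE, verbose = FALSE) {
  regularizer <- match.arg(regularizer)
  if (regularizer %in% c("red", "cwred") && is.null(denoiser))
    stop(sprintf("regularizer '%s' requires a denoiser", regularizer))
  structure(list(regularizer = regularizer, grid = grid,
                 maxIterations = maxIterations, patience = patience,
                 denoiser = denoiser, lambdaFixed = lambdaFixed,
                 schedule = schedule, initialResolution = initialResolution,
                 keepIntermediates = keepIntermediates, verbose = verbose),
            class = "RefinementConfig")
}

#' Gold-standard half-set refinement
#'
#' Splits the images alternately (odd/even index) into two half-sets and
#' iterates E-step and the selected M-step independently on each half.
#' Each iteration the per-shell signal power and the nominal resolution
#' (FSC at 0.143) are re-estimated from the FSC between the two
#' *unregularized* half-maps (B/K) of that iteration, which carry the
#' newly aligned signal; the regularized M-step output is then produced
#' with that tau2.  For `"cwred"` the confidence weight is re-evaluated
#' each iteration from the current nominal resolution.
#'
#' @param ds a [SimulatedDataset-class].
#' @param config a [refinementConfig()].
#' @return A list with `states` (one [RefinementState-class] per
#'   iteration), `final` (last state), `bestPose` (per-image argmax-
#'   responsibility grid index from the final E-step, for angular-error
#'   evaluation), `grid`, and, when requested, `intermediates`: a list of
#'   records with the unregularized half-map (`xtilde`, a
#'   [RealVolume-class]), `half`, `iteration`, `fscHalf` and
#'   `nominalResolution`.
#' @export
runRefinement <- function(ds, config = refinementConfig()) {
  stopifnot(is(ds, "SimulatedDataset"), inherits(config, "RefinementConfig"))
  n <- dim(ds@images)[1]
  vx <- ds@groundTruth@voxelSize
  grid <- if (is.null(config$grid)) poseGridUniform() else config$grid
  m <- imageCount(ds)
  halves <- list(datasetSubset(ds, seq(1, m, by = 2)),
                 datasetSubset(ds, seq(2, m, by = 2)))

  ## initial reference: low-pass filtered scaled ground truth
  gtScaled <- realVolume(ds@groundTruth@data * ds@intensityScale, vx)
  ref0 <- forwardTransform(lowpassVolume(gtScaled, config$initialResolution))
  models <- list(ref0, ref0)

  bestRes <- Inf; stall <- 0L
  states <- list(); intermediates <- list()
  halfIdx <- list(seq(1, m, by = 2), seq(2, m, by = 2))
  bestPose <- integer(m)  # per-image argmax responsibility, last E-step

  for (it in seq_len(config$maxIterations)) {
    ## E-steps of both halves, then FSC/tau2 from the *unregularized*
    ## half-maps of this iteration: they carry the newly aligned signal
    ## beyond the previous resolution, which the regularized maps (zeroed
    ## by the Wiener filter past the prior cutoff) cannot
    es <- lapply(1:2, function(k) estep(halves[[k]], models[[k]], grid))
    for (k in 1:2) bestPose[halfIdx[[k]]] <- es[[k]]$bestPose
    xtF <- lapply(1:2, function(k) {
      x <- es[[k]]$acc@B / es[[k]]$acc@K
      x[!is.finite(x)] <- 0i
      fourierVolume(.hermitianize(x), vx)
    })
    fh <- fsc(xtF[[1]], xtF[[2]])
    nominalRes <- as.numeric(resolutionAt(fh, 0.143, vx))
    tau2 <- estimateTau2(xtF[[1]], xtF[[2]])
    lam <- switch(config$regularizer,
      gaussian = 0,
      red = if (is.null(config$lambdaFixed)) 1 else config$lambdaFixed,
      cwred = lambdaAt(config$schedule, nominalRes))
    for (k in 1:2) {
      models[[k]] <- if (config$regularizer == "gaussian" || lam == 0)
        mstepGaussian(es[[k]]$acc, tau2)
      else
        mstepRed(es[[k]]$acc, tau2, config$denoiser, lam)
      if (anyNA(models[[k]]@data))
        stop(sprintf(
          "refinement diverged: NaN in half-map %d at iteration %d",
          k, it))
      if (config$keepIntermediates)
        intermediates[[length(intermediates) + 1L]] <-
          list(half = k, iteration = it,
               xtilde = inverseTransform(xtF[[k]], tol = Inf),
               fscHalf = fh, nominalResolution = nominalRes)
    }
    st <- new("RefinementState", halfModels = models, tau2 = tau2,
              fscHalf = fh, iteration = as.integer(it),
              nominalResolution = nominalRes, lambda = lam)
    states[[it]] <- st
    if (config$verbose)
      message(sprintf("iter %2d: nominal %.2f A, lambda %.3f",
                      it, nominalRes, lam))
    if (nominalRes < bestRes - 1e-6) {
      bestRes <- nominalRes; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) break
    }
  }
  if (!length(states)) {
    ## zero iterations requested: report the initial reference unchanged
    ns <- n %/% 2 + 1L
    states <- list(new("RefinementState", halfModels = models,
                       tau2 = shellProfile(rep(0, ns), "tau2"),
                       fscHalf = shellProfile(rep(1, ns), "fsc"),
                       iteration = 0L,
                       nominalResolution = config$initialResolution,
                       lambda = 0))
  }
  list(states = states, final = states[[length(states)]],
       bestPose = bestPose, grid = grid,
       intermediates = if (config$keepIntermediates) intermediates else NULL)
}

## B/K unregularized map in real space (zeros where K = 0).
.unregularizedMap <- function(acc) {
  x <- acc@B / acc@K
  x[!is.finite(x)] <- 0i
  inverseTransform(fourierVolume(.hermitianize(x), acc@voxelSize),
                   tol = Inf)
}
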