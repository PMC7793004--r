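## Regularization by denoising (RED) and confidence-weighted RED M-steps.
##
## The denoiser f is a real-space operator; each RED update therefore
## inverse-transforms the unregularized map B/K, denoises it under the
## standardization contract, transforms back, and combines:
##     x = (B + lambda * tau^-2 * F_denoised) / (K + tau^-2)
## per Fourier voxel with shell-wise tau^-2.  lambda = 0 reduces the update
## to the Gaussian-prior Wiener step; tau^-2 = 0 returns the unregularized
## map untouched, so the denoiser acts on the map that contains the most
## recent alignment information.

#' Apply a denoiser under the standardization contract
#'
#' The input volume is standardized (subtract the volume mean, divide by
#' the volume standard deviation) before the denoiser is applied, and the
#' standardization is reversed afterwards:
#' `mean + sd * f((v - mean)/sd)`.  The identity denoiser therefore
#' returns the input exactly, and any fixed denoiser commutes with affine
#' rescaling of its input.
#'
#' @param d a [DenoiserHandle-class].
#' @param v a [RealVolume-class] with nonzero standard deviation.
#' @return The denoised [RealVolume-class].
#' @export
standardizedDenoise <- function(d, v) {
  stopifnot(is(d, "DenoiserHandle"), is(v, "RealVolume"))
  mu <- mean(v@data)
  s <- sd(as.vector(v@data))
  if (!is.finite(s) || s == 0)
    stop("standardizedDenoise: zero-variance (degenerate) input volume")
  z <- (v@data - mu) / s
  out <- d@apply(z)
  if (!identical(dim(out), dim(v@data)))
    stop("denoiser changed the grid dimensions")
  ## denoisers acting as the exact identity reverse bit-exactly
  if (identical(out, z)) return(v)
  realVolume(mu + s * out, v@voxelSize)
}

#' Denoiser-based estimate of the prior score
#'
#' Tweedie/score-matching identity: for an MMSE denoiser f matched to
#' additive Gaussian noise of variance `noiseVar`, the gradient of the
#' log-prior is approximated by `(f(x) - x) / noiseVar`.  Evaluated with
#' `noiseVar` equal to the per-shell signal power tau^2 this yields the
#' modulated prior gradient tau^-2 (f(x) - x) used by the RED M-step,
#' which suppresses the denoiser where certainty in the data is high.
#'
#' @param x a [RealVolume-class].
#' @param d a [DenoiserHandle-class].
#' @param noiseVar positive scalar noise variance the denoiser is matched
#'   to.
#' @return A [RealVolume-class] holding the score estimate.
#' @export
redGradient <- function(x, d, noiseVar) {
  stopifnot(noiseVar > 0)
  fx <- standardizedDenoise(d, x)
  realVolume((fx@data - x@data) / noiseVar, x@voxelSize)
}

#' RED / CW-RED M-step
#'
#' Computes the unregularized map `x~ = B/K` (zeros where K = 0), denoises
#' it in real space under the standardization contract, and combines per
#' Fourier voxel:
#' `x = (B + lambda * tau^-2 * F~) / (K + tau^-2)`
#' with `F~` the spectrum of the denoised map and `tau^-2` the shell value.
#' `lambda = 0` reproduces [mstepGaussian()] bit-exactly (the denoiser is
#' not invoked); shells with `tau2 = 0` return `lambda * F~` (the
#' infinite-regularization limit of the update).
#'
#' @param acc an [AccumulatorPair-class].
#' @param tau2 a [ShellProfile-class] of per-shell signal power.
#' @param d a [DenoiserHandle-class].
#' @param lambda confidence weight in \[0, 1\].
#' @return A [FourierVolume-class].
#' @export
mstepRed <- function(acc, tau2, d, lambda) {
  stopifnot(lambda >= 0, lambda <= 1)
  if (lambda == 0) return(mstepGaussian(acc, tau2))
  n <- dim(acc@B)[1]
  xt <- .unregularizedMap(acc)
  ft <- standardizedDenoise(d, xt)
  Ft <- forwardTransform(ft)@data
  tinv <- .tauInvGrid(tau2, n)
  x <- (acc@B + lambda * tinv * Ft) / (acc@K + tinv)
  inf <- !is.finite(tinv)
  x[inf] <- lambda * Ft[inf]
  x[!is.finite(x)] <- 0i
  fourierVolume(x, acc@voxelSize)
}

#' Confidence weight at a nominal resolution
#'
#' 0 at resolutions worse than (>=) `resZero`, 1 at resolutions better
#' than (<=) `resOne`, linear in resolution between the boundaries:
#' `(resZero - res) / (resZero - resOne)`, clamped to \[0, 1\].
#'
#' @param schedule a [LambdaSchedule-class].
#' @param nominalResolution half-map FSC resolution in Angstrom (> 0).
#' @return numeric confidence weight in \[0, 1\].
#' @export
lambdaAt <- function(schedule, nominalResolution) {
  stopifnot(is(schedule, "LambdaSchedule"), all(nominalResolution > 0))
  lam <- (schedule@resZero - nominalResolution) /
    (schedule@resZero - schedule@resOne)
  pmin(1, pmax(0, lam))
}

#' Single-pass denoiser assessment
#'
#' For each (unregularized map, ground truth, nominal resolution) triple
#' the denoiser is applied once and the ratio
#' `||denoised - gt||_p / ||unregularized - gt||_p` is recorded; ratios are
#' averaged within nominal-resolution bins.  Ratios below 1 mean the
#' denoiser moved the map closer to the ground truth.
#'
#' @param pairs list of records, each with elements `input` (a
#'   [RealVolume-class] unregularized map), `groundTruth` (a
#'   [RealVolume-class]) and `nominalResolution` (Angstrom);
#'   [TrainingPair-class] objects whose `target` is the ground truth are
#'   also accepted.
#' @param d a [DenoiserHandle-class].
#' @param p norm order, 1 or 2.
#' @param breaks resolution bin edges in Angstrom (default: 6 equal bins
#'   over the observed range).
#' @return A data.frame with `binCenter`, `meanRatio`, `n`; per-pair
#'   ratios in attribute `"ratios"`, skipped-pair count in `"skipped"`.
#' @export
singlePassAssessment <- function(pairs, d, p = 2, breaks = NULL) {
  stopifnot(length(pairs) >= 1, p %in% c(1, 2))
  getRec <- function(x) {
    if (is(x, "TrainingPair"))
      list(input = x@input, groundTruth = x@target,
           nominalResolution = x@nominalResolution)
    else x
  }
  recs <- lapply(pairs, getRec)
  lpnorm <- function(a, p) if (p == 1) sum(abs(a)) else sqrt(sum(a^2))
  ratios <- numeric(0); res <- numeric(0); skipped <- 0L
  for (r in recs) {
    denom <- lpnorm(r$input@data - r$groundTruth@data, p)
    if (denom == 0) {
      warning("skipping pair with zero unregularized error")
      skipped <- skipped + 1L
      next
    }
    den <- standardizedDenoise(d, r$input)
    ratios <- c(ratios, lpnorm(den@data - r$groundTruth@data, p) / denom)
    res <- c(res, r$nominalResolution)
  }
  if (is.null(breaks)) {
    rng <- range(res)
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    breaks <- seq(rng[1], rng[2], length.out = 7)
  }
  bin <- findInterval(res, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  centers <- (head(breaks, -1) + tail(breaks, -1)) / 2
  out <- data.frame(
    binCenter = centers,
    meanRatio = vapply(seq_along(centers), function(b) {
      if (any(bin == b)) mean(ratios[bin == b]) else NA_real_
    }, numeric(1)),
    n = vapply(seq_along(centers), function(b) sum(bin == b), numeric(1)))
  attr(out, "ratios") <- data.frame(nominalResolution = res, ratio = ratios)
  attr(out, "skipped") <- skipped
  out
}
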