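## The linear TEM image-formation operator H_g and its exact adjoint.
##
## By the Fourier slice theorem the 2D transform of a projection is the
## central plane of the 3D transform perpendicular to the viewing axis:
## y(k) = CTF(k) * exp(-2 pi i k.t / N) * x(R [kx, ky, 0]').
## Slices are extracted by trilinear interpolation with no oversampling
## padding; the adjoint scatters with the transposed interpolation weights
## so the dot-product identity <H x, y> = <x, H* y> is exact by
## construction.

## Trilinear gather: continuous 1-based coordinates from pose rotation.
## Returns list(idx = 8 x npix matrix of linear indices or NA, w = weights).
.sliceSupport <- function(R, n) {
  g <- .gridGeometry(n, 2L)
  k2 <- rbind(as.vector(g$kx), as.vector(g$ky), 0)
  p <- R %*% k2 + n %/% 2 + 1          # continuous 1-based coordinates
  f0 <- floor(p)
  d <- p - f0
  npix <- ncol(p)
  idx <- matrix(NA_real_, 8, npix)
  w <- matrix(0, 8, npix)
  corner <- 0L
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    corner <- corner + 1L
    ix <- f0[1, ] + cx; iy <- f0[2, ] + cy; iz <- f0[3, ] + cz
    ok <- ix >= 1 & ix <= n & iy >= 1 & iy <= n & iz >= 1 & iz <= n
    wt <- (if (cx) d[1, ] else 1 - d[1, ]) *
          (if (cy) d[2, ] else 1 - d[2, ]) *
          (if (cz) d[3, ] else 1 - d[3, ])
    lin <- (iz - 1) * n * n + (iy - 1) * n + ix
    lin[!ok] <- NA_real_
    idx[corner, ] <- lin
    w[corner, ] <- wt
  }
  list(idx = idx, w = w)
}

## Phase ramp for an in-plane translation t (pixels), vector over pixels.
.translationPhase <- function(trans, n) {
  if (all(trans == 0)) return(rep(1 + 0i, n * n))
  g <- .gridGeometry(n, 2L)
  exp(-2i * pi * (as.vector(g$kx) * trans[1] + as.vector(g$ky) * trans[2]) / n)
}

## Core slice extraction: complex vector of length n^2 (no phase, no CTF).
.extractSlice <- function(fdata, R) {
  n <- dim(fdata)[1]
  sup <- .sliceSupport(R, n)
  out <- complex(n * n)
  for (corner in 1:8) {
    lin <- sup$idx[corner, ]
    ok <- !is.na(lin)
    if (any(ok))
      out[ok] <- out[ok] + sup$w[corner, ok] * fdata[lin[ok]]
  }
  out
}

#' Project a Fourier volume into a 2D frequency image
#'
#' Applies the forward operator H_g: central-slice extraction at the pose's
#' rotation (trilinear interpolation), the translation phase ramp and, when
#' enabled, the CTF.  Linear in the volume.
#'
#' @param x a [FourierVolume-class] (Hermitian).
#' @param pose a [Pose-class].
#' @param ctf a [CTFParams-class]; defaults to disabled (CTF = 1).
#' @return complex N x N matrix in the centred frequency convention.
#' @export
project <- function(x, pose, ctf = ctfParams(enabled = FALSE)) {
  stopifnot(is(x, "FourierVolume"), is(pose, "Pose"))
  n <- gridSide(x)
  y <- .extractSlice(x@data, pose@rotation) *
    .translationPhase(pose@translation, n) *
    .ctfImage(ctf, n, x@voxelSize)
  matrix(y, n, n)
}

## Scatter transpose of .extractSlice: adds bvec (complex) into B and kvec
## (real, >= 0) into K along the rotated slice.  Exact transpose of the
## gather above, so project/adjointInsert form an adjoint pair.
.scatterSlice <- function(bvec, kvec, R, B, K) {
  n <- dim(B)[1]
  sup <- .sliceSupport(R, n)
  allIdx <- as.vector(sup$idx)
  ok <- !is.na(allIdx)
  wAll <- as.vector(sup$w)[ok]
  idxAll <- allIdx[ok]
  bAll <- rep(bvec, each = 8)[ok] * wAll
  kAll <- rep(kvec, each = 8)[ok] * wAll
  ## rowsum() collapses duplicate voxel indices in one pass
  acc <- rowsum(cbind(Re(bAll), Im(bAll), kAll), idxAll)
  tgt <- as.integer(rownames(acc))
  B[tgt] <- B[tgt] + complex(real = acc[, 1], imaginary = acc[, 2])
  K[tgt] <- K[tgt] + acc[, 3]
  list(B = B, K = K)
}

#' Backproject one image into an accumulator pair
#'
#' The exact adjoint of [project()]: multiplies the image by the CTF, the
#' conjugate translation phase and `weight`, and scatters it into the
#' numerator volume B with the transposed trilinear weights; `weight *
#' CTF^2` is scattered into the diagonal kernel K at the same voxels.
#' Division by the noise power (the Wiener weighting of the E-step) is the
#' caller's responsibility.
#'
#' @param img complex N x N frequency image.
#' @param pose a [Pose-class].
#' @param ctf a [CTFParams-class].
#' @param weight scalar responsibility weight (>= 0).
#' @param acc an [AccumulatorPair-class] to update.
#' @return The updated [AccumulatorPair-class].
#' @export
adjointInsert <- function(img, pose, ctf = ctfParams(enabled = FALSE),
                          weight = 1, acc) {
  stopifnot(is(acc, "AccumulatorPair"))
  n <- dim(acc@B)[1]
  if (!all(dim(img) == c(n, n)))
    stop("image side does not match accumulator")
  if (weight == 0) return(acc)
  cvec <- .ctfImage(ctf, n, acc@voxelSize)
  ph <- .translationPhase(pose@translation, n)
  bvec <- as.vector(img) * Conj(ph) * cvec * weight
  kvec <- cvec^2 * weight
  upd <- .scatterSlice(bvec, kvec, pose@rotation, acc@B, acc@K)
  initialize(acc, B = upd$B, K = upd$K)
}
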