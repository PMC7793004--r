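## Grid conventions, unitary transforms and radial-shell bookkeeping.
##
## Frequency indexing: integer lattice k in [-N/2, N/2)^3, shell
## s = round(|k|), s = 0..N/2.  Transforms are unitary so Parseval's
## identity holds without scale factors, which keeps SNR and power
## bookkeeping trivial.  The real-space rotation centre is 0-based index
## N/2 along each axis (even-N FFT convention).

## Cached lattice geometry for side N and dimensionality nd (2 or 3):
## continuous radius, shell index (NA beyond Nyquist) and frequency values.
.gridGeometry <- function(n, nd = 3L) {
  key <- sprintf("geom_%d_%d", n, nd)
  g <- .cryoredCache[[key]]
  if (!is.null(g)) return(g)
  k <- .freqValues(n)
  if (nd == 3L) {
    kx <- array(rep(k, times = n * n), c(n, n, n))
    ky <- array(rep(rep(k, each = n), times = n), c(n, n, n))
    kz <- array(rep(k, each = n * n), c(n, n, n))
    r <- sqrt(kx^2 + ky^2 + kz^2)
  } else {
    kx <- matrix(k, n, n)
    ky <- matrix(k, n, n, byrow = TRUE)
    kz <- NULL
    r <- sqrt(kx^2 + ky^2)
  }
  s <- as.integer(round(r))
  s[s > n %/% 2] <- NA_integer_
  g <- list(kx = kx, ky = ky, kz = kz, r = r, shell = s,
            nShells = n %/% 2 + 1L)
  assign(key, g, envir = .cryoredCache)
  g
}

.unitaryFFT <- function(a, inverse = FALSE) {
  nd <- length(dim(a))
  n <- dim(a)[1]
  .centerShift(fft(.centerShift(a), inverse = inverse)) / n^(nd / 2)
}

#' Forward Fourier transform of a real volume
#'
#' Unitary, centred 3D transform: Parseval's identity holds exactly and the
#' DC component sits at 1-based index N/2 + 1.  A density centred on the
#' volume centre transforms to a real, positive spectrum.
#'
#' @param v a [RealVolume-class].
#' @return A [FourierVolume-class] with Hermitian-symmetric data.
#' @seealso [inverseTransform()]
#' @export
forwardTransform <- function(v) {
  stopifnot(is(v, "RealVolume"))
  f <- .unitaryFFT(v@data + 0i)
  fourierVolume(f, v@voxelSize)
}

#' Inverse Fourier transform back to real space
#'
#' Requires Hermitian symmetry within tolerance; the (tiny) imaginary
#' residual of the inverse transform is discarded.
#'
#' @param f a [FourierVolume-class].
#' @param tol relative tolerance on the imaginary residual (default 1e-5).
#' @return A [RealVolume-class].
#' @export
inverseTransform <- function(f, tol = 1e-5) {
  stopifnot(is(f, "FourierVolume"))
  a <- .unitaryFFT(f@data, inverse = TRUE)
  re <- Re(a); im <- Im(a)
  nrm <- sqrt(sum(re^2) + sum(im^2))
  if (nrm > 0 && sqrt(sum(im^2)) / nrm > tol)
    stop("inverseTransform: input violates Hermitian symmetry beyond tolerance")
  realVolume(re, f@voxelSize)
}

## 2D counterparts used for projection images (internal).
.forwardTransform2 <- function(img) .unitaryFFT(img + 0i)
.inverseTransform2 <- function(f) Re(.unitaryFFT(f, inverse = TRUE))

#' Relative Hermitian-symmetry error of a centred frequency grid
#'
#' Compares voxels against their Friedel mates `data(-k) = Conj(data(k))`
#' over the sub-grid where the mate exists (the k = -N/2 planes have no
#' partner on an even grid and are excluded).
#'
#' @param f a [FourierVolume-class] or complex array.
#' @return relative error (0 for a perfectly Hermitian grid).
#' @export
hermitianError <- function(f) {
  a <- if (is(f, "FourierVolume")) f@data else f
  n <- dim(a)[1]
  ix <- 2:n
  g <- a[ix, ix, ix, drop = FALSE]
  grev <- Conj(a[rev(ix), rev(ix), rev(ix), drop = FALSE])
  denom <- sqrt(sum(Mod(g)^2))
  if (denom == 0) return(0)
  sqrt(sum(Mod(g - grev)^2)) / denom
}

## Project a centred complex grid onto the Hermitian-symmetric subspace.
.hermitianize <- function(a) {
  n <- dim(a)[1]
  ix <- 2:n
  g <- a[ix, ix, ix, drop = FALSE]
  a[ix, ix, ix] <- (g + Conj(a[rev(ix), rev(ix), rev(ix), drop = FALSE])) / 2
  dc <- n %/% 2 + 1L
  a[dc, dc, dc] <- Re(a[dc, dc, dc]) + 0i
  a
}

#' Radial shell average
#'
#' Averages a (real or complex) cubic grid over the radial shells
#' s = round(|k|); voxels beyond Nyquist (s > N/2) are excluded.
#'
#' @param x a [FourierVolume-class], or a real/complex cubic 3D array in the
#'   centred frequency convention.
#' @param kind `kind` for the returned profile.
#' @return A [ShellProfile-class] of length N/2 + 1.
#' @export
shellAverage <- function(x, kind = "power") {
  a <- if (is(x, "FourierVolume")) x@data else x
  .shellProfileFromValues(.shellMean(a), kind)
}

.shellProfileFromValues <- function(v, kind) {
  v[!is.finite(v)] <- 0
  if (kind == "fsc") v <- pmin(1, pmax(-1, v))
  shellProfile(v, kind)
}

## Mean per shell of a numeric/complex array; returns numeric vector.
.shellMean <- function(a) {
  n <- dim(a)[1]
  g <- .gridGeometry(n, length(dim(a)))
  keep <- !is.na(g$shell)
  v <- a[keep]
  if (is.complex(v)) v <- Re(v)
  s <- g$shell[keep]
  sums <- rowsum(v, s)
  cnts <- rowsum(rep(1, length(s)), s)
  out <- numeric(g$nShells)
  out[as.integer(rownames(sums)) + 1L] <- sums / cnts
  out
}

## Sum per shell (used by FSC); returns numeric vector of length N/2+1.
.shellSum <- function(v, shellIdx, nShells) {
  if (is.complex(v)) v <- Re(v)
  sums <- rowsum(v, shellIdx)
  out <- numeric(nShells)
  out[as.integer(rownames(sums)) + 1L] <- sums
  out
}

#' Multiply a frequency grid by a per-shell profile
#'
#' Each Fourier voxel is scaled by the profile value at its shell; voxels
#' beyond the Nyquist sphere use the outermost shell value so an all-ones
#' profile leaves the volume unchanged.  Hermitian symmetry is preserved
#' because the factor depends only on |k|.
#'
#' @param f a [FourierVolume-class].
#' @param p a [ShellProfile-class] of length N/2 + 1 (or a bare numeric
#'   vector of that length).
#' @return A filtered [FourierVolume-class].
#' @export
applyShellFilter <- function(f, p) {
  stopifnot(is(f, "FourierVolume"))
  vals <- if (is(p, "ShellProfile")) p@values else as.numeric(p)
  n <- dim(f@data)[1]
  if (length(vals) != n %/% 2 + 1L)
    stop(sprintf("profile length %d does not match grid (need %d)",
                 length(vals), n %/% 2 + 1L))
  fourierVolume(f@data * .shellFactorGrid(vals, n), f@voxelSize)
}

## Expand a per-shell vector onto the 3D lattice (shells clamped at N/2).
.shellFactorGrid <- function(vals, n) {
  g <- .gridGeometry(n, 3L)
  s <- pmin(as.integer(round(g$r)), n %/% 2)
  array(vals[s + 1L], dim = c(n, n, n))
}

## Same for the 2D image lattice.
.shellFactorImage <- function(vals, n) {
  g <- .gridGeometry(n, 2L)
  s <- pmin(as.integer(round(g$r)), n %/% 2)
  matrix(vals[s + 1L], n, n)
}

#' Low-pass filter a real volume to a target resolution
#'
#' Soft (raised-cosine over two shells) cutoff at the shell corresponding
#' to `resolution` Angstrom.
#'
#' @param v a [RealVolume-class].
#' @param resolution target resolution in Angstrom.
#' @param soft number of shells over which the edge is rolled off.
#' @return The filtered [RealVolume-class].
#' @export
lowpassVolume <- function(v, resolution, soft = 2) {
  n <- gridSide(v)
  sCut <- n * v@voxelSize / resolution
  s <- 0:(n %/% 2)
  prof <- ifelse(s <= sCut, 1,
                 ifelse(s >= sCut + soft, 0,
                        0.5 * (1 + cos(pi * (s - sCut) / soft))))
  inverseTransform(applyShellFilter(forwardTransform(v), prof))
}
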