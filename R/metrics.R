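## Assessment metrics: Fourier shell correlation, threshold-crossing
## resolution estimates, soft solvent masks and angular-error statistics.

#' Fourier shell correlation between two volumes
#'
#' Per shell s: `Re(sum v1 Conj(v2)) / sqrt(sum |v1|^2 sum |v2|^2)`.
#' Shells where either volume has zero power (and empty shells) are
#' reported as 0 and flagged in the `"zeroPower"` attribute.
#'
#' @param v1,v2 [FourierVolume-class] objects on the same grid, or
#'   [RealVolume-class] objects (transformed internally).
#' @return A [ShellProfile-class] of kind `"fsc"`.
#' @export
fsc <- function(v1, v2) {
  if (is(v1, "RealVolume")) v1 <- forwardTransform(v1)
  if (is(v2, "RealVolume")) v2 <- forwardTransform(v2)
  a <- v1@data; b <- v2@data
  if (!identical(dim(a), dim(b))) stop("volumes must share a grid")
  n <- dim(a)[1]
  g <- .gridGeometry(n, 3L)
  keep <- !is.na(g$shell)
  s <- g$shell[keep]
  num <- .shellSum(Re(a[keep] * Conj(b[keep])), s, g$nShells)
  p1 <- .shellSum(Mod(a[keep])^2, s, g$nShells)
  p2 <- .shellSum(Mod(b[keep])^2, s, g$nShells)
  denom <- sqrt(p1 * p2)
  zero <- denom == 0
  vals <- numeric(g$nShells)
  vals[!zero] <- num[!zero] / denom[!zero]
  out <- .shellProfileFromValues(vals, "fsc")
  attr(out, "zeroPower") <- which(zero) - 1L
  out
}

#' Resolution at an FSC threshold
#'
#' Scans shells in ascending frequency for the first drop below
#' `threshold` and converts the linearly interpolated crossing frequency to
#' Angstrom.  A profile that never drops reports the Nyquist resolution
#' (2 * voxel size); a profile already below threshold at shell 1 reports
#' the worst representable resolution (N * voxel size) with attribute
#' `"belowAtFirstShell"`.
#'
#' @param p a [ShellProfile-class] of kind `"fsc"` (or numeric vector).
#' @param threshold FSC threshold in (0, 1); 0.143 for half-map FSC, 0.5
#'   for comparisons against a ground truth.
#' @param voxelSize Angstrom per voxel of the underlying grid.
#' @return resolution in Angstrom.
#' @export
resolutionAt <- function(p, threshold = 0.143, voxelSize = 1) {
  vals <- if (is(p, "ShellProfile")) p@values else as.numeric(p)
  nShells <- length(vals)
  n <- 2L * (nShells - 1L)       # grid side implied by the profile length
  boxA <- n * voxelSize
  cross <- NA_real_
  for (s in seq(2L, nShells)) {  # shell index s-1 in 0-based terms
    if (vals[s] < threshold) {
      s0 <- s - 2L; s1 <- s - 1L  # 0-based bracketing shells
      f0 <- vals[s - 1L]; f1 <- vals[s]
      frac <- (f0 - threshold) / (f0 - f1)
      cross <- s0 + frac * (s1 - s0)
      break
    }
  }
  if (is.na(cross)) return(2 * voxelSize)  # holds to Nyquist
  if (cross < 1) {
    ## dropped within the first shell: worst representable resolution
    out <- boxA
    attr(out, "belowAtFirstShell") <- TRUE
    return(out)
  }
  max(2 * voxelSize, boxA / cross)
}

#' Soft-edged spherical solvent mask
#'
#' 1 inside `radius`, raised-cosine falloff across `edgeWidth`, 0 outside;
#' the value at `radius + edgeWidth/2` is exactly 0.5.
#'
#' @param side grid side N.
#' @param voxelSize Angstrom per voxel.
#' @param radius mask radius in Angstrom.
#' @param edgeWidth soft-edge width in Angstrom.
#' @return A [RealVolume-class] with values in \[0, 1\].
#' @export
softMask <- function(side, voxelSize, radius = 0.4 * side * voxelSize,
                     edgeWidth = 5 * voxelSize) {
  if (radius + edgeWidth > side * voxelSize / 2)
    stop("mask (radius + edgeWidth) exceeds half the box size")
  g <- .gridGeometry(side, 3L)
  r <- g$r * voxelSize
  m <- if (edgeWidth == 0) as.numeric(r <= radius) else
    ifelse(r <= radius, 1,
           ifelse(r >= radius + edgeWidth, 0,
                  0.5 * (1 + cos(pi * pmin(1, pmax(0, (r - radius) /
                                                        edgeWidth))))))
  realVolume(array(m, dim(r)), voxelSize)
}

#' Apply a soft solvent mask before FSC evaluation
#' @param v a [RealVolume-class].
#' @param mask a [RealVolume-class] mask on the same grid.
#' @return The masked [RealVolume-class].
#' @export
applyMask <- function(v, mask) {
  realVolume(v@data * mask@data, v@voxelSize)
}

#' Angular errors between true and estimated rotations
#'
#' Per image the error is the rotation angle of the relative rotation
#' (axis-angle magnitude, in \[0, pi\]).
#'
#' @param truePoses list of [Pose-class] (or rotation matrices).
#' @param estimatedPoses list of the same length.
#' @param breaks histogram breaks in radians (default 18 bins over
#'   \[0, pi\]).
#' @return A list with `perImageError` (radians), `median` and `histogram`
#'   (output of [graphics::hist()]-free binning: counts per bin).
#' @export
angularError <- function(truePoses, estimatedPoses,
                         breaks = seq(0, pi, length.out = 19)) {
  if (length(truePoses) != length(estimatedPoses))
    stop("pose lists must have equal length")
  getR <- function(p) if (is(p, "Pose")) p@rotation else p
  err <- mapply(function(a, b) rotationAngle(getR(a), getR(b)),
                truePoses, estimatedPoses)
  cnt <- tabulate(findInterval(err, breaks, rightmost.closed = TRUE),
                  nbins = length(breaks) - 1L)
  list(perImageError = err, median = stats::median(err),
       histogram = list(breaks = breaks, counts = cnt))
}
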