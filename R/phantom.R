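## Synthetic ground-truth volumes: chain-like assemblies of Gaussian blobs
## emulating compact single-chain protein densities at the 40-100 kDa
## scale.  Deterministic given the seed; support is confined strictly
## inside a sphere of radius 0.45 N voxels so a solvent margin always
## exists for masking.

#' Phantom specification
#'
#' @param side grid side N (even).
#' @param voxelSize Angstrom per voxel.
#' @param nBlobs number of Gaussian blobs along the chain.
#' @param blobSigmaRange range (Angstrom) of per-blob standard deviations.
#' @param chainStep step length (Angstrom) of the blob random walk.
#' @param elongation anisotropy factor >= 1; walk steps are stretched along
#'   one axis so larger values yield more elongated particles.
#' @param seed integer seed; the phantom is a pure function of the spec.
#' @return A list of class `"PhantomSpec"`.
#' @export
phantomSpec <- function(side = 48, voxelSize = 3.0, nBlobs = 24,
                        blobSigmaRange = c(3, 6), chainStep = 5,
                        elongation = 1.5, seed = 1) {
  stopifnot(side %% 2 == 0, nBlobs >= 1, all(blobSigmaRange > 0),
            chainStep > 0, elongation >= 1)
  structure(list(side = as.integer(side), voxelSize = voxelSize,
                 nBlobs = as.integer(nBlobs),
                 blobSigmaRange = blobSigmaRange, chainStep = chainStep,
                 elongation = elongation, seed = as.integer(seed)),
            class = "PhantomSpec")
}

#' Generate a phantom ground-truth volume
#'
#' A seeded random walk of Gaussian blobs: blob centres step by
#' `chainStep` Angstrom in random directions (stretched by `elongation`
#' along a random axis), each blob contributing a unit-amplitude isotropic
#' Gaussian.  Centres are reflected back so that, allowing 3 sigma of blob
#' extent, all density stays inside the 0.45 N sphere; any residual tail
#' outside that sphere is clipped to zero.
#'
#' @param spec a [phantomSpec()].
#' @return A nonnegative [RealVolume-class].
#' @export
makePhantom <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  set.seed(spec$seed)
  n <- spec$side
  vx <- spec$voxelSize
  rmaxVox <- 0.45 * n
  sigmas <- runif(spec$nBlobs, spec$blobSigmaRange[1], spec$blobSigmaRange[2])
  ## walk in voxel units, centre of volume at 0-based index n/2
  stretchAxis <- sample(3, 1)
  scale3 <- rep(1, 3); scale3[stretchAxis] <- spec$elongation
  centres <- matrix(0, spec$nBlobs, 3)
  posn <- c(0, 0, 0)
  for (b in seq_len(spec$nBlobs)) {
    lim <- rmaxVox - 3 * sigmas[b] / vx - 1
    posn <- pmax(-lim, pmin(lim, posn))
    centres[b, ] <- posn
    stp <- rnorm(3) * scale3
    stp <- stp / sqrt(sum(stp^2)) * spec$chainStep / vx
    posn <- posn + stp
  }
  g <- .gridGeometry(n, 3L)  # kx/ky/kz double as centred voxel offsets
  dat <- array(0, c(n, n, n))
  for (b in seq_len(spec$nBlobs)) {
    s2 <- (sigmas[b] / vx)^2
    d2 <- (g$kx - centres[b, 1])^2 + (g$ky - centres[b, 2])^2 +
      (g$kz - centres[b, 3])^2
    dat <- dat + exp(-d2 / (2 * s2))
  }
  dat[g$r >= rmaxVox] <- 0
  realVolume(dat, vx)
}

#' Principal second-moment ratio of a density
#'
#' Ratio of the largest to the smallest eigenvalue of the density-weighted
#' covariance of voxel coordinates; 1 for an isotropic blob, > 1 for
#' elongated particles.
#'
#' @param v a nonnegative [RealVolume-class].
#' @return numeric ratio >= 1.
#' @export
momentAnisotropy <- function(v) {
  n <- gridSide(v)
  g <- .gridGeometry(n, 3L)
  w <- as.vector(v@data)
  w <- w / sum(w)
  xyz <- cbind(as.vector(g$kx), as.vector(g$ky), as.vector(g$kz))
  mu <- colSums(xyz * w)
  xc <- sweep(xyz, 2, mu)
  cv <- crossprod(xc * w, xc)
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  ev[1] / ev[3]
}
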