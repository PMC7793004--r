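## Rotation utilities: quaternions, uniform SO(3) sampling and
## quasi-uniform deterministic pose grids.

#' Convert a unit quaternion to a rotation matrix
#' @param q numeric(4) quaternion (w, x, y, z); normalized internally.
#' @return 3x3 rotation matrix.
#' @export
quaternionToMatrix <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

#' Convert a rotation matrix to a unit quaternion
#' @param R 3x3 rotation matrix.
#' @return numeric(4) quaternion (w, x, y, z) with w >= 0.
#' @export
matrixToQuaternion <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q <- q / sqrt(sum(q^2))
  if (q[1] < 0) q <- -q
  q
}

#' Draw rotations uniformly from SO(3)
#'
#' Uses the quaternion method (four standard normal deviates, normalized),
#' which is exactly uniform under the Haar measure and seedable.
#'
#' @param n number of rotations.
#' @return list of 3x3 rotation matrices.
#' @export
randomRotations <- function(n) {
  lapply(seq_len(n), function(i) quaternionToMatrix(rnorm(4)))
}

## Deterministic quasi-uniform directions on the sphere (Fibonacci spiral).
.fibonacciDirections <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

## Rotation taking e_z to direction d, followed by in-plane rotation psi.
.rotationFromDirection <- function(d, psi) {
  z <- d / sqrt(sum(d^2))
  up <- if (abs(z[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  x <- up - sum(up * z) * z
  x <- x / sqrt(sum(x^2))
  y <- c(z[2] * x[3] - z[3] * x[2], z[3] * x[1] - z[1] * x[3],
         z[1] * x[2] - z[2] * x[1])
  Rd <- cbind(x, y, z)
  cp <- cos(psi); sp <- sin(psi)
  Rp <- matrix(c(cp, -sp, 0, sp, cp, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Rd %*% Rp
}

#' Build a quasi-uniform global pose grid
#'
#' Deterministic fixed-resolution covering of SO(3): a Fibonacci spiral of
#' viewing directions crossed with equispaced in-plane rotations, optionally
#' crossed with an integer in-plane translation lattice.  The prior over
#' poses is uniform.
#'
#' @param nDirections number of viewing directions (default 74).
#' @param nPsi number of in-plane angles per direction (default 8; the
#'   default grid therefore has 592 orientations).
#' @param translationMax half-width of the translation search in pixels; 0
#'   searches no translations, a positive value adds the integer lattice
#'   \[-translationMax, translationMax\]^2.
#' @return A [PoseGrid-class].
#' @export
poseGridUniform <- function(nDirections = 74, nPsi = 8, translationMax = 0) {
  dirs <- .fibonacciDirections(nDirections)
  psis <- seq(0, 2 * pi, length.out = nPsi + 1)[seq_len(nPsi)]
  rots <- vector("list", nDirections * nPsi)
  k <- 0L
  for (i in seq_len(nDirections)) {
    for (p in psis) {
      k <- k + 1L
      rots[[k]] <- .rotationFromDirection(dirs[i, ], p)
    }
  }
  if (translationMax > 0) {
    tvals <- seq(-floor(translationMax), floor(translationMax))
    tr <- as.matrix(expand.grid(tx = tvals, ty = tvals))
    nT <- nrow(tr)
    rots <- rep(rots, each = nT)
    trans <- tr[rep(seq_len(nT), times = k), , drop = FALSE]
  } else {
    trans <- matrix(0, k, 2)
  }
  n <- length(rots)
  new("PoseGrid", rotations = rots,
      translations = unname(as.matrix(trans)),
      logPrior = rep(-log(n), n))
}

#' Build a pose grid from explicit poses
#' @param poses list of [Pose-class] objects.
#' @param logPrior optional unnormalized log prior weights.
#' @return A [PoseGrid-class] with normalized prior.
#' @export
poseGridFromPoses <- function(poses, logPrior = NULL) {
  n <- length(poses)
  if (is.null(logPrior)) logPrior <- rep(0, n)
  logPrior <- logPrior - .logSumExp(logPrior)
  new("PoseGrid",
      rotations = lapply(poses, function(p) p@rotation),
      translations = do.call(rbind, lapply(poses, function(p) p@translation)),
      logPrior = logPrior)
}

#' Angle of the relative rotation between two rotations
#' @param R1,R2 3x3 rotation matrices.
#' @return rotation angle of `t(R1) %*% R2` in radians, in \[0, pi\].
#' @export
rotationAngle <- function(R1, R2) {
  tr <- sum(diag(crossprod(R1, R2)))
  acos(pmin(1, pmax(-1, (tr - 1) / 2)))
}
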