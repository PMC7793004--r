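#' @import methods
#' @importFrom stats rnorm runif var sd fft optimize uniroot
#' @importFrom utils head tail modifyList
NULL

## Internal cache for shell-index lookups and frequency lattices, keyed by
## grid side.  Values never change for a given N, so this is safe.
.cryoredCache <- new.env(parent = emptyenv())

#' RealVolume: a cubic real-space density map
#'
#' Holds a cubic 3D grid of real densities with an isotropic voxel size in
#' Angstrom.  The volume centre (rotation origin for all pose operations)
#' sits at 0-based index `N/2` along each axis; the side length `N` must be
#' even.
#'
#' @slot data numeric 3D array, cubic with even side.
#' @slot voxelSize numeric(1), Angstrom per voxel, > 0.
#' @slot origin numeric(3), origin in Angstrom (metadata only).
#' @export
setClass("RealVolume",
  representation(data = "array", voxelSize = "numeric", origin = "numeric"),
  prototype(voxelSize = 1, origin = c(0, 0, 0))
)

setValidity("RealVolume", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L || length(unique(d)) != 1L)
    return("data must be a cubic 3D array")
  if (d[1] %% 2L != 0L)
    return("side length must be even")
  if (is.complex(object@data))
    return("data must be real-valued")
  if (!all(is.finite(object@data)))
    return("data must be finite")
  if (length(object@voxelSize) != 1L || !is.finite(object@voxelSize) ||
      object@voxelSize <= 0)
    return("voxelSize must be a single positive number")
  TRUE
})

#' Construct a RealVolume
#'
#' @param data cubic real 3D array with even side.
#' @param voxelSize Angstrom per voxel.
#' @param origin optional 3-vector origin in Angstrom.
#' @return A [RealVolume-class] object.
#' @export
realVolume <- function(data, voxelSize = 1, origin = c(0, 0, 0)) {
  new("RealVolume", data = data, voxelSize = as.numeric(voxelSize),
      origin = as.numeric(origin))
}

#' FourierVolume: a cubic frequency-space model
#'
#' Complex 3D Fourier coefficients on the centred integer frequency lattice
#' k in \[-N/2, N/2)^3 (index i maps to k = i - 1 - N/2, 1-based).  For a
#' model of a real density the grid is Hermitian-symmetric,
#' `data(-k) = Conj(data(k))`.
#'
#' @slot data complex 3D array.
#' @slot voxelSize numeric(1), Angstrom per voxel of the real-space grid.
#' @export
setClass("FourierVolume",
  representation(data = "array", voxelSize = "numeric"),
  prototype(voxelSize = 1)
)

setValidity("FourierVolume", function(object) {
  d <- dim(object@data)
  if (length(d) != 3L || length(unique(d)) != 1L)
    return("data must be a cubic 3D array")
  if (d[1] %% 2L != 0L)
    return("side length must be even")
  if (!is.complex(object@data))
    return("data must be complex")
  if (object@voxelSize <= 0)
    return("voxelSize must be positive")
  TRUE
})

#' Construct a FourierVolume
#' @param data cubic complex 3D array (centred frequency convention).
#' @param voxelSize Angstrom per voxel.
#' @return A [FourierVolume-class] object.
#' @export
fourierVolume <- function(data, voxelSize = 1) {
  new("FourierVolume", data = data, voxelSize = as.numeric(voxelSize))
}

#' ShellProfile: one value per radial frequency shell
#'
#' Radial shells are indexed s = 0..N/2 with s = round(|k|) on the integer
#' frequency lattice.  `kind` records the semantics: Fourier shell
#' correlation (`fsc`, bounded in \[-1, 1\]), signal power (`tau2`), noise
#' power (`sigma2`) or raw spectral power (`power`); the three power kinds
#' must be nonnegative.
#'
#' @slot values numeric vector of length N/2 + 1.
#' @slot kind character(1), one of "fsc", "tau2", "sigma2", "power".
#' @export
setClass("ShellProfile",
  representation(values = "numeric", kind = "character"),
  prototype(kind = "power")
)

setValidity("ShellProfile", function(object) {
  if (length(object@kind) != 1L ||
      !object@kind %in% c("fsc", "tau2", "sigma2", "power"))
    return("kind must be one of fsc, tau2, sigma2, power")
  v <- object@values
  if (length(v) < 1L || anyNA(v))
    return("values must be non-empty and free of NA")
  if (object@kind == "fsc" && any(v < -1 - 1e-9 | v > 1 + 1e-9))
    return("fsc values must lie in [-1, 1]")
  if (object@kind != "fsc" && any(v < 0))
    return(sprintf("%s values must be nonnegative", object@kind))
  TRUE
})

#' Construct a ShellProfile
#' @param values numeric vector, one value per shell 0..N/2.
#' @param kind one of `"fsc"`, `"tau2"`, `"sigma2"`, `"power"`.
#' @return A [ShellProfile-class] object.
#' @export
shellProfile <- function(values, kind = "power") {
  new("ShellProfile", values = as.numeric(values), kind = kind)
}

#' Pose: a particle orientation and in-plane shift
#'
#' @slot rotation 3x3 orthonormal matrix with determinant +1.
#' @slot translation numeric(2), in-plane shift in pixels.
#' @export
setClass("Pose",
  representation(rotation = "matrix", translation = "numeric"),
  prototype(translation = c(0, 0))
)

setValidity("Pose", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L)))
    return("rotation must be 3x3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-9)
    return("rotation must be orthonormal within 1e-9")
  if (abs(det(R) - 1) > 1e-9)
    return("rotation must have determinant +1")
  if (length(object@translation) != 2L || anyNA(object@translation))
    return("translation must be a finite 2-vector")
  TRUE
})

#' Construct a Pose
#' @param rotation 3x3 rotation matrix.
#' @param translation in-plane shift in pixels (2-vector).
#' @return A [Pose-class] object.
#' @export
pose <- function(rotation = diag(3), translation = c(0, 0)) {
  new("Pose", rotation = rotation, translation = as.numeric(translation))
}

#' CTFParams: contrast transfer function parameters
#'
#' @slot defocus defocus in micrometre (positive = underfocus).
#' @slot sphericalAberration Cs in millimetre.
#' @slot amplitudeContrast amplitude-contrast fraction in \[0, 1\].
#' @slot voltage acceleration voltage in kV.
#' @slot enabled logical; when FALSE the CTF is identically 1.
#' @export
setClass("CTFParams",
  representation(defocus = "numeric", sphericalAberration = "numeric",
                 amplitudeContrast = "numeric", voltage = "numeric",
                 enabled = "logical"),
  prototype(defocus = 1, sphericalAberration = 2.7, amplitudeContrast = 0.1,
            voltage = 300, enabled = TRUE)
)

setValidity("CTFParams", function(object) {
  if (object@amplitudeContrast < 0 || object@amplitudeContrast > 1)
    return("amplitudeContrast must lie in [0, 1]")
  if (object@voltage <= 0) return("voltage must be positive")
  TRUE
})

#' Construct CTF parameters
#' @param defocus defocus in micrometre.
#' @param sphericalAberration Cs in millimetre.
#' @param amplitudeContrast amplitude-contrast fraction.
#' @param voltage acceleration voltage in kV.
#' @param enabled logical; disabled CTF evaluates to 1 everywhere.
#' @return A [CTFParams-class] object.
#' @export
ctfParams <- function(defocus = 1, sphericalAberration = 2.7,
                      amplitudeContrast = 0.1, voltage = 300,
                      enabled = TRUE) {
  new("CTFParams", defocus = defocus,
      sphericalAberration = sphericalAberration,
      amplitudeContrast = amplitudeContrast, voltage = voltage,
      enabled = enabled)
}

#' ProjectionImage: one particle image in frequency space
#'
#' @slot data complex 2D array (centred frequency convention), side N.
#' @slot ctf a [CTFParams-class].
#' @slot sigma2 a [ShellProfile-class] of per-shell noise power.
#' @export
setClass("ProjectionImage",
  representation(data = "array", ctf = "CTFParams", sigma2 = "ShellProfile")
)

setValidity("ProjectionImage", function(object) {
  d <- dim(object@data)
  if (length(d) != 2L || d[1] != d[2]) return("data must be square 2D")
  if (!is.complex(object@data)) return("data must be complex")
  if (any(object@sigma2@values <= 0))
    return("sigma2 must be strictly positive")
  TRUE
})

#' Construct a ProjectionImage
#' @param data square complex 2D array.
#' @param ctf a [CTFParams-class].
#' @param sigma2 a [ShellProfile-class] (kind `"sigma2"`) of noise power.
#' @return A [ProjectionImage-class] object.
#' @export
projectionImage <- function(data, ctf = ctfParams(enabled = FALSE),
                            sigma2 = shellProfile(rep(1, dim(data)[1] / 2 + 1),
                                                  "sigma2")) {
  new("ProjectionImage", data = data, ctf = ctf, sigma2 = sigma2)
}

#' PoseGrid: discrete sampling of the orientation/translation search space
#'
#' @slot rotations list of 3x3 rotation matrices.
#' @slot translations numeric matrix, one row (2 columns, pixels) per pose.
#' @slot logPrior numeric log prior weight per pose; logsumexp equals 0.
#' @export
setClass("PoseGrid",
  representation(rotations = "list", translations = "matrix",
                 logPrior = "numeric")
)

setValidity("PoseGrid", function(object) {
  n <- length(object@rotations)
  if (n < 1L) return("grid must contain at least one pose")
  if (nrow(object@translations) != n || ncol(object@translations) != 2L)
    return("translations must be an n x 2 matrix")
  if (length(object@logPrior) != n)
    return("logPrior length must match pose count")
  lse <- .logSumExp(object@logPrior)
  if (abs(lse) > 1e-6)
    return("logPrior must be normalized (logsumexp = 0)")
  TRUE
})

#' AccumulatorPair: backprojection numerator B and diagonal kernel K
#'
#' `B` is the responsibility-weighted, noise-whitened backprojection of the
#' data; `K` is the matching diagonal of the (noise-whitened) normal
#' operator.  The unregularized reconstruction is `B/K`.
#'
#' @slot B complex 3D array (Hermitian-symmetric).
#' @slot K real nonnegative 3D array.
#' @slot voxelSize Angstrom per voxel.
#' @export
setClass("AccumulatorPair",
  representation(B = "array", K = "array", voxelSize = "numeric"),
  prototype(voxelSize = 1)
)

setValidity("AccumulatorPair", function(object) {
  if (!identical(dim(object@B), dim(object@K)))
    return("B and K must have identical dimensions")
  if (!is.complex(object@B)) return("B must be complex")
  if (is.complex(object@K)) return("K must be real")
  if (any(object@K < -1e-12)) return("K must be nonnegative")
  TRUE
})

#' Construct an empty AccumulatorPair
#' @param side grid side N.
#' @param voxelSize Angstrom per voxel.
#' @return An [AccumulatorPair-class] with all-zero B and K.
#' @export
accumulatorPair <- function(side, voxelSize = 1) {
  z <- array(0, c(side, side, side))
  new("AccumulatorPair", B = z + 0i, K = z, voxelSize = voxelSize)
}

#' RefinementState: per-iteration record of a half-set refinement
#'
#' @slot halfModels list of two [FourierVolume-class] half-set models.
#' @slot tau2 [ShellProfile-class] of per-shell signal power.
#' @slot fscHalf [ShellProfile-class], half-map FSC.
#' @slot iteration integer iteration counter (0 = initial reference).
#' @slot nominalResolution numeric, Angstrom (half-map FSC at 0.143).
#' @slot lambda numeric in \[0, 1\], denoiser confidence weight used.
#' @export
setClass("RefinementState",
  representation(halfModels = "list", tau2 = "ShellProfile",
                 fscHalf = "ShellProfile", iteration = "integer",
                 nominalResolution = "numeric", lambda = "numeric")
)

setValidity("RefinementState", function(object) {
  if (length(object@halfModels) != 2L)
    return("halfModels must contain exactly two models")
  if (any(object@tau2@values < 0)) return("tau2 must be nonnegative")
  if (object@lambda < 0 || object@lambda > 1)
    return("lambda must lie in [0, 1]")
  vx <- object@halfModels[[1]]@voxelSize
  if (object@nominalResolution < 2 * vx - 1e-9)
    return("nominal resolution cannot beat Nyquist")
  TRUE
})

#' SimulatedDataset: a synthetic projection data set
#'
#' Images are stored as a complex array `N x N x m` in the centred frequency
#' convention, together with per-image pose and CTF metadata and the shared
#' per-shell noise power.
#'
#' @slot images complex array N x N x m.
#' @slot poses list of [Pose-class], the true generating poses.
#' @slot meta data.frame with one row per image (defocus, etc.).
#' @slot groundTruth [RealVolume-class] used to generate the data.
#' @slot sigma2 [ShellProfile-class], per-shell noise power (shared).
#' @slot intensityScale numeric scalar applied to the ground truth.
#' @slot snr numeric, mean per-pixel signal variance over noise variance.
#' @slot noiseSd numeric, real-space noise standard deviation.
#' @export
setClass("SimulatedDataset",
  representation(images = "array", poses = "list", meta = "data.frame",
                 groundTruth = "RealVolume", sigma2 = "ShellProfile",
                 intensityScale = "numeric", snr = "numeric",
                 noiseSd = "numeric")
)

setValidity("SimulatedDataset", function(object) {
  d <- dim(object@images)
  if (length(d) != 3L || d[1] != d[2]) return("images must be N x N x m")
  if (length(object@poses) != d[3])
    return("poses must match the number of images")
  if (object@snr < 0) return("snr must be nonnegative")
  TRUE
})

#' DenoiserHandle: a pluggable real-space volume denoiser
#'
#' `apply` maps a standardized (zero-mean, unit-sd) real 3D array to a real
#' 3D array on the same grid; use [standardizedDenoise()] to apply it to an
#' arbitrary volume with the standardization contract.
#'
#' @slot name identifier used in registries and logs.
#' @slot apply function(array) -> array on the same grid.
#' @slot trainedOn provenance: one of "refinement_intermediates",
#'   "gaussian_noise", "classical", "identity", "oracle".
#' @export
setClass("DenoiserHandle",
  representation(name = "character", apply = "function",
                 trainedOn = "character")
)

#' Construct a DenoiserHandle
#' @param name identifier.
#' @param apply function mapping a standardized real 3D array to one of the
#'   same dimensions.
#' @param trainedOn provenance tag.
#' @return A [DenoiserHandle-class].
#' @export
denoiserHandle <- function(name, apply, trainedOn = "classical") {
  new("DenoiserHandle", name = name, apply = apply, trainedOn = trainedOn)
}

#' LambdaSchedule: resolution-dependent denoiser confidence weight
#'
#' The confidence weight is 0 at nominal resolutions worse than `resZero`
#' (pure Gaussian prior), 1 at resolutions better than `resOne` (pure
#' denoiser prior) and linearly interpolated between the two boundaries.
#'
#' @slot resZero Angstrom; at and beyond this resolution lambda = 0.
#' @slot resOne Angstrom; at and below this resolution lambda = 1.
#' @export
setClass("LambdaSchedule",
  representation(resZero = "numeric", resOne = "numeric"),
  prototype(resZero = 10, resOne = 4.5)
)

setValidity("LambdaSchedule", function(object) {
  if (!(object@resZero > object@resOne && object@resOne > 0))
    return("need resZero > resOne > 0")
  TRUE
})

#' Construct a LambdaSchedule
#' @param resZero resolution (Angstrom) at which the weight reaches 0.
#' @param resOne resolution (Angstrom) at which the weight reaches 1.
#' @return A [LambdaSchedule-class].
#' @export
lambdaSchedule <- function(resZero = 10, resOne = 4.5) {
  new("LambdaSchedule", resZero = resZero, resOne = resOne)
}

#' TrainingPair: one denoiser training example
#'
#' @slot input [RealVolume-class], an unregularized intermediate map.
#' @slot target [RealVolume-class], the FSC-coarsened ground truth.
#' @slot nominalResolution Angstrom at which the input was produced.
#' @slot phantomId identifier of the source phantom (for splits).
#' @export
setClass("TrainingPair",
  representation(input = "RealVolume", target = "RealVolume",
                 nominalResolution = "numeric", phantomId = "character")
)

## ---- show methods -------------------------------------------------------

setMethod("show", "RealVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("RealVolume %dx%dx%d, voxel %.3g A, range [%.3g, %.3g]\n",
              d[1], d[2], d[3], object@voxelSize,
              min(object@data), max(object@data)))
})

setMethod("show", "FourierVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("FourierVolume %dx%dx%d, voxel %.3g A, power %.4g\n",
              d[1], d[2], d[3], object@voxelSize,
              sum(Mod(object@data)^2)))
})

setMethod("show", "ShellProfile", function(object) {
  cat(sprintf("ShellProfile<%s> %d shells: %s\n", object@kind,
              length(object@values),
              paste(signif(head(object@values, 5), 3), collapse = ", ")))
})

setMethod("show", "PoseGrid", function(object) {
  cat(sprintf("PoseGrid with %d poses (max |shift| %.2g px)\n",
              length(object@rotations), max(abs(object@translations))))
})

setMethod("show", "SimulatedDataset", function(object) {
  d <- dim(object@images)
  cat(sprintf(
    "SimulatedDataset: %d images %dx%d, scale %.4g, SNR %.4g, noise sd %.3g\n",
    d[3], d[1], d[2], object@intensityScale, object@snr, object@noiseSd))
})

setMethod("show", "DenoiserHandle", function(object) {
  cat(sprintf("DenoiserHandle '%s' (trained on: %s)\n",
              object@name, object@trainedOn))
})

setMethod("show", "RefinementState", function(object) {
  cat(sprintf(
    "RefinementState iter %d: nominal %.2f A, lambda %.3f\n",
    object@iteration, object@nominalResolution, object@lambda))
})

## ---- accessors ----------------------------------------------------------

#' Grid side of a volume-like object
#' @param x a RealVolume, FourierVolume or AccumulatorPair.
#' @return integer side length N.
#' @export
gridSide <- function(x) {
  if (is(x, "RealVolume") || is(x, "FourierVolume")) dim(x@data)[1]
  else if (is(x, "AccumulatorPair")) dim(x@B)[1]
  else stop("unsupported type for gridSide")
}

#' Voxel size in Angstrom
#' @param x a volume-like object.
#' @return numeric voxel size.
#' @export
voxelSize <- function(x) x@voxelSize

#' Raw data array of a volume-like object
#' @param x a RealVolume, FourierVolume or ProjectionImage.
#' @return the underlying array.
#' @export
volumeData <- function(x) x@data

#' Per-shell values of a ShellProfile
#' @param x a [ShellProfile-class].
#' @return numeric vector of shell values.
#' @export
shellValues <- function(x) x@values

#' Number of poses in a PoseGrid
#' @param x a [PoseGrid-class].
#' @return integer pose count.
#' @export
poseCount <- function(x) length(x@rotations)

#' Number of images in a dataset
#' @param x a [SimulatedDataset-class].
#' @return integer image count.
#' @export
imageCount <- function(x) dim(x@images)[3]
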