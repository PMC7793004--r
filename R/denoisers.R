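## Denoiser handles and the by-name registry.  Handles operate on
## standardized real-space arrays (see standardizedDenoise()).

.denoiserRegistry <- new.env(parent = emptyenv())

#' Register a denoiser under its name
#' @param d a [DenoiserHandle-class].
#' @return The handle, invisibly.
#' @export
registerDenoiser <- function(d) {
  stopifnot(is(d, "DenoiserHandle"))
  assign(d@name, d, envir = .denoiserRegistry)
  invisible(d)
}

#' Look up a denoiser by name
#'
#' Built-ins: `"identity"` and `"classical:<strength>"` (for example
#' `"classical:1.5"`); trained handles registered via [registerDenoiser()]
#' or loaded with [loadDenoiser()] are found by their name.
#'
#' @param name character identifier.
#' @return A [DenoiserHandle-class].
#' @export
getDenoiser <- function(name) {
  if (exists(name, envir = .denoiserRegistry, inherits = FALSE))
    return(get(name, envir = .denoiserRegistry, inherits = FALSE))
  if (name == "identity") return(identityDenoiser())
  if (grepl("^classical:", name))
    return(classicalDenoiser(as.numeric(sub("^classical:", "", name))))
  stop(sprintf("unknown denoiser '%s'", name))
}

#' The identity denoiser
#' @return A [DenoiserHandle-class] returning its input unchanged.
#' @export
identityDenoiser <- function() {
  denoiserHandle("identity", function(a) a, trainedOn = "identity")
}

#' Training-free classical denoiser (Gaussian smoothing)
#'
#' Real-space Gaussian smoothing of standard deviation `strength` voxels,
#' applied as the frequency-space factor `exp(-2 pi^2 strength^2 |k|^2 /
#' N^2)`.  Strength 0 is the identity (factor exactly 1); larger strengths
#' never increase the power of any shell.
#'
#' @param strength nonnegative smoothing strength in voxels.
#' @return A [DenoiserHandle-class].
#' @export
classicalDenoiser <- function(strength) {
  stopifnot(strength >= 0)
  apply <- function(a) {
    if (strength == 0) return(a)
    n <- dim(a)[1]
    g <- .gridGeometry(n, 3L)
    fac <- exp(-2 * pi^2 * strength^2 * g$r^2 / n^2)
    Re(.unitaryFFT(.unitaryFFT(a + 0i) * fac, inverse = TRUE))
  }
  denoiserHandle(sprintf("classical:%g", strength), apply,
                 trainedOn = "classical")
}

#' Persist a trained denoiser
#'
#' Serializes the handle's weights and architecture (a U-Net handle built
#' by [trainDenoiser()]) to a single portable file.
#'
#' @param d a [DenoiserHandle-class] carrying `weights`/`spec` attributes.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
saveDenoiser <- function(d, path) {
  payload <- list(name = d@name, trainedOn = d@trainedOn,
                  weights = attr(d, "weights"), spec = attr(d, "spec"))
  if (is.null(payload$weights))
    stop("only trained denoisers with serializable weights can be saved")
  saveRDS(payload, path)
  invisible(path)
}

#' Load a trained denoiser from file
#' @param path file written by [saveDenoiser()].
#' @param register register the handle under its stored name.
#' @return A [DenoiserHandle-class].
#' @export
loadDenoiser <- function(path, register = TRUE) {
  payload <- readRDS(path)
  d <- .unetHandle(payload$weights, payload$spec, payload$name,
                   payload$trainedOn)
  if (register) registerDenoiser(d)
  d
}
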