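## External-reconstruction file protocol: the refinement engine writes the
## accumulators B (as a real/imaginary MRC pair over the full Fourier
## grid) and K, plus a STAR table with the current per-shell FSC and tau2;
## an external worker watches for those files, applies an M-step handler
## and delivers the resulting real-space map atomically (temp file +
## rename), so the appearance of the result file signals completeness.
## This is a documented dialect of the exchange, inspectable with
## standard MRC tools; it is not byte-compatible with other engines.

#' Describe an external-reconstruction job
#'
#' @param dir directory holding the exchange files.
#' @param halfId 1 or 2.
#' @param pollInterval seconds between checks for the input files.
#' @param timeout seconds to wait before giving up.
#' @return list of class `"ExternalReconstructJob"` with the file paths.
#' @export
externalReconstructJob <- function(dir, halfId = 1, pollInterval = 0.2,
                                   timeout = 30) {
  stopifnot(halfId %in% 1:2, pollInterval > 0)
  base <- file.path(dir, sprintf("half%d", halfId))
  structure(list(
    halfId = as.integer(halfId),
    bRealPath = paste0(base, "_B_real.mrc"),
    bImagPath = paste0(base, "_B_imag.mrc"),
    kPath = paste0(base, "_K.mrc"),
    metadataPath = paste0(base, "_shells.star"),
    resultPath = paste0(base, "_result.mrc"),
    pollInterval = pollInterval, timeout = timeout),
    class = "ExternalReconstructJob")
}

#' Write the engine side of an external-reconstruction exchange
#'
#' @param acc an [AccumulatorPair-class].
#' @param fscHalf a [ShellProfile-class] (kind fsc).
#' @param tau2 a [ShellProfile-class] (kind tau2).
#' @param job an [externalReconstructJob()].
#' @return `job`, invisibly.
#' @export
writeExternalJob <- function(acc, fscHalf, tau2, job) {
  writeMRC(realVolume(Re(acc@B), acc@voxelSize), job$bRealPath)
  writeMRC(realVolume(Im(acc@B), acc@voxelSize), job$bImagPath)
  writeMRC(realVolume(acc@K, acc@voxelSize), job$kPath)
  writeStarTable(
    data.frame(shellIndex = seq_along(tau2@values) - 1L,
               fsc = fscHalf@values, tau2 = tau2@values),
    job$metadataPath, block = "external_reconstruct")
  invisible(job)
}

#' Serve one external-reconstruction job
#'
#' Waits (up to `timeout`) for the B/K/metadata files, reads them back,
#' invokes `handler(acc, fsc, tau2)` (which must return a
#' [FourierVolume-class] or [RealVolume-class]) and writes the real-space
#' result to the job's result path atomically.  If the result file already
#' exists the handler is not invoked (idempotent re-serve).
#'
#' @param job an [externalReconstructJob()].
#' @param handler function(acc, fscHalf, tau2) -> volume; for example a
#'   wrapper around [mstepGaussian()] or [mstepRed()].
#' @return The result path, invisibly; attribute `"skipped"` is TRUE when
#'   an existing result was kept.
#' @export
serveExternalReconstruct <- function(job, handler) {
  if (file.exists(job$resultPath)) {
    message("external reconstruct: result already present, skipping")
    out <- invisible(job$resultPath)
    attr(out, "skipped") <- TRUE
    return(out)
  }
  needed <- c(job$bRealPath, job$bImagPath, job$kPath, job$metadataPath)
  waited <- 0
  while (!all(file.exists(needed))) {
    if (waited >= job$timeout)
      stop(sprintf("timed out after %gs waiting for %s", job$timeout,
                   paste(needed[!file.exists(needed)], collapse = ", ")))
    Sys.sleep(job$pollInterval)
    waited <- waited + job$pollInterval
  }
  bRe <- readMRC(job$bRealPath)
  bIm <- readMRC(job$bImagPath)
  k <- readMRC(job$kPath)
  if (!identical(dim(bRe@data), dim(k@data)))
    stop(sprintf("protocol error: B grid %s does not match K grid %s",
                 paste(dim(bRe@data), collapse = "x"),
                 paste(dim(k@data), collapse = "x")))
  meta <- readStarTable(job$metadataPath, "external_reconstruct")
  acc <- new("AccumulatorPair",
             B = bRe@data + 1i * bIm@data, K = pmax(k@data, 0),
             voxelSize = bRe@voxelSize)
  fscHalf <- shellProfile(pmin(1, pmax(-1, meta$fsc)), "fsc")
  tau2 <- shellProfile(pmax(0, meta$tau2), "tau2")
  res <- handler(acc, fscHalf, tau2)
  if (is(res, "FourierVolume")) res <- inverseTransform(res, tol = Inf)
  tmp <- paste0(job$resultPath, ".tmp")
  writeMRC(res, tmp)
  file.rename(tmp, job$resultPath)
  out <- invisible(job$resultPath)
  attr(out, "skipped") <- FALSE
  out
}
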