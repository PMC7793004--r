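## Dataset persistence: MRC stack of real-space images + STAR metadata
## (pose quaternions, translations, defocus) + ground-truth MRC + a plain
## text manifest.  Everything round-trips through standard formats so
## simulated data are inspectable with ecosystem tools.

#' Save a simulated dataset to a directory
#'
#' @param ds a [SimulatedDataset-class].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
saveDataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vx <- ds@groundTruth@voxelSize
  writeMRC(ds@groundTruth, file.path(dir, "ground_truth.mrc"))
  writeMRC(datasetRealImages(ds), file.path(dir, "images.mrc"),
           voxelSize = vx)
  q <- t(vapply(ds@poses, function(p) matrixToQuaternion(p@rotation),
                numeric(4)))
  tr <- t(vapply(ds@poses, function(p) p@translation, numeric(2)))
  writeStarTable(
    data.frame(imageIndex = seq_len(imageCount(ds)),
               q1 = q[, 1], q2 = q[, 2], q3 = q[, 3], q4 = q[, 4],
               tx = tr[, 1], ty = tr[, 2],
               defocus = ds@meta$defocus),
    file.path(dir, "particles.star"), block = "particles")
  writeLines(c(
    sprintf("intensityScale: %.17g", ds@intensityScale),
    sprintf("noiseSd: %.17g", ds@noiseSd),
    sprintf("snr: %.17g", ds@snr),
    sprintf("voxelSize: %.17g", vx)),
    file.path(dir, "dataset_manifest.txt"))
  invisible(dir)
}

#' Load a simulated dataset saved by [saveDataset()]
#' @param dir dataset directory.
#' @return A [SimulatedDataset-class].
#' @export
loadDataset <- function(dir) {
  gt <- readMRC(file.path(dir, "ground_truth.mrc"))
  stack <- readMRC(file.path(dir, "images.mrc"))
  if (is(stack, "RealVolume")) stack <- list(data = stack@data,
                                             voxelSize = stack@voxelSize)
  meta <- readStarTable(file.path(dir, "particles.star"), "particles")
  man <- .readManifest(file.path(dir, "dataset_manifest.txt"))
  n <- dim(stack$data)[1]
  m <- dim(stack$data)[3]
  images <- array(0i, c(n, n, m))
  for (i in seq_len(m))
    images[, , i] <- .forwardTransform2(stack$data[, , i])
  poses <- lapply(seq_len(m), function(i)
    pose(quaternionToMatrix(c(meta$q1[i], meta$q2[i], meta$q3[i],
                              meta$q4[i])),
         c(meta$tx[i], meta$ty[i])))
  sig2 <- if (man$noiseSd > 0) man$noiseSd^2 else 1
  new("SimulatedDataset", images = images, poses = poses,
      meta = data.frame(defocus = meta$defocus),
      groundTruth = gt,
      sigma2 = shellProfile(rep(sig2, n %/% 2 + 1L), "sigma2"),
      intensityScale = man$intensityScale, snr = man$snr,
      noiseSd = man$noiseSd)
}

.readManifest <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, ":\\s*")
  out <- lapply(kv, function(x) {
    v <- suppressWarnings(as.numeric(x[2]))
    if (is.na(v)) x[2] else v
  })
  names(out) <- vapply(kv, `[[`, character(1), 1)
  out
}
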