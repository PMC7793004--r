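## Minimal MRC2014 reader/writer (mode 2, 32-bit float, little endian).
## Volumes are nx = ny = nz cubes; image stacks use nz = number of images.
## The voxel size round-trips through the cell dimensions (cella = n *
## voxel), and read(write(v)) is bit-exact for float32 data.

.mrcWriteHeader <- function(con, nx, ny, nz, voxel, dmin, dmax, dmean,
                            ispg = 1L) {
  writeBin(as.integer(c(nx, ny, nz)), con, size = 4, endian = "little")
  writeBin(2L, con, size = 4, endian = "little")               # mode 2
  writeBin(integer(3), con, size = 4, endian = "little")       # nstart
  writeBin(as.integer(c(nx, ny, nz)), con, size = 4, endian = "little")
  writeBin(as.numeric(c(nx, ny, nz) * voxel), con, size = 4,
           endian = "little")                                  # cella
  writeBin(c(90, 90, 90), con, size = 4, endian = "little")    # cellb
  writeBin(1:3, con, size = 4, endian = "little")              # mapc/r/s
  writeBin(as.numeric(c(dmin, dmax, dmean)), con, size = 4,
           endian = "little")
  writeBin(as.integer(c(ispg, 0L)), con, size = 4, endian = "little")
  writeBin(raw(100), con)                                      # extra
  writeBin(numeric(3), con, size = 4, endian = "little")       # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)             # machst
  writeBin(0, con, size = 4, endian = "little")                # rms
  writeBin(1L, con, size = 4, endian = "little")               # nlabl
  lab <- charToRaw(formatC("cryored", width = -80))
  writeBin(c(lab, raw(80 - length(lab))), con)
  writeBin(raw(80 * 9), con)
}

#' Write a real volume (or image stack) as MRC2014
#'
#' @param v a [RealVolume-class], or a 3D numeric array (stack) plus
#'   `voxelSize`.
#' @param path output path.
#' @param voxelSize required when `v` is a bare array.
#' @return `path`, invisibly.
#' @export
writeMRC <- function(v, path, voxelSize = NULL) {
  if (is(v, "RealVolume")) {
    a <- v@data; voxel <- v@voxelSize; ispg <- 1L
  } else {
    a <- v
    if (is.null(voxelSize)) stop("voxelSize required for bare arrays")
    voxel <- voxelSize
    ispg <- if (length(unique(dim(a))) == 1L) 1L else 0L
  }
  con <- file(path, "wb")
  on.exit(close(con))
  .mrcWriteHeader(con, dim(a)[1], dim(a)[2], dim(a)[3], voxel,
                  min(a), max(a), mean(a), ispg)
  writeBin(as.numeric(a), con, size = 4, endian = "little")
  invisible(path)
}

#' Read an MRC2014 volume
#'
#' Supports mode 2 (float32) and mode 0 (int8); other modes raise a
#' format error, as do truncated files.
#'
#' @param path MRC file path.
#' @return A [RealVolume-class] (cubic data) or, for stacks, a list with
#'   `data` (array) and `voxelSize`.
#' @export
readMRC <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 1024) stop("corrupt MRC header: file too small")
  con <- file(path, "rb")
  on.exit(close(con))
  dims <- readBin(con, integer(), 3, size = 4, endian = "little")
  mode <- readBin(con, integer(), 1, size = 4, endian = "little")
  invisible(readBin(con, integer(), 3, size = 4, endian = "little"))
  mxyz <- readBin(con, integer(), 3, size = 4, endian = "little")
  cella <- readBin(con, numeric(), 3, size = 4, endian = "little")
  if (any(dims <= 0) || any(dims > 1e4)) stop("corrupt MRC header")
  if (!mode %in% c(0L, 2L))
    stop(sprintf("unsupported MRC mode %d", mode))
  nvox <- prod(as.numeric(dims))
  bytes <- if (mode == 2L) 4 else 1
  seek(con, 92)
  nsymbt <- readBin(con, integer(), 1, size = 4, endian = "little")
  if (sz < 1024 + nsymbt + nvox * bytes)
    stop("corrupt MRC file: truncated data section")
  seek(con, 1024 + nsymbt)
  vals <- if (mode == 2L)
    readBin(con, numeric(), nvox, size = 4, endian = "little")
  else
    as.numeric(readBin(con, integer(), nvox, size = 1, signed = TRUE))
  if (length(vals) < nvox) stop("corrupt MRC file: truncated data section")
  voxel <- if (mxyz[1] > 0) cella[1] / mxyz[1] else 1
  a <- array(vals, dims)
  if (length(unique(dims)) == 1L) realVolume(a, voxel)
  else list(data = a, voxelSize = voxel)
}
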