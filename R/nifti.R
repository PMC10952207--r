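# Minimal NIfTI-1 I/O (uncompressed .nii, native endianness).
# No pre-installed R package in this stack reads NIfTI, so the package carries
# its own small reader/writer for the subset it emits: 3D/4D volumes,
# int32 / float32 / float64 data, sform affine.

NIFTI_DT <- list(int16 = 4L, int32 = 8L, float32 = 16L, float64 = 64L,
                 uint8 = 2L)

#' Write a volume as NIfTI-1
#'
#' Writes an uncompressed `.nii` file with the sform set from a 4x4
#' voxel-to-world affine (0-based indices, mm). Integer arrays are stored as
#' int32, doubles as float64 (or float32 when `datatype = "float32"`).
#'
#' @param vol 3D or 4D array.
#' @param path output path (`.nii`).
#' @param world 4x4 voxel-index-to-world-mm affine.
#' @param datatype one of `"int32"`, `"float32"`, `"float64"`; default chosen
#'   from the storage mode of `vol`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path, world = diag(4), datatype = NULL) {
  d <- dim(vol)
  stopifnot(length(d) %in% c(3, 4))
  if (is.null(datatype))
    datatype <- if (is.integer(vol) || all(vol == round(vol))) "int32" else "float64"
  dt <- NIFTI_DT[[datatype]]
  if (is.null(dt)) stop("unsupported datatype: ", datatype)
  bitpix <- c(`2` = 8L, `4` = 16L, `8` = 32L, `16` = 32L, `64` = 64L)[as.character(dt)]
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(348L, con, size = 4)                      # sizeof_hdr
  writeBin(raw(36), con)                             # unused
  dimv <- integer(8)
  dimv[1] <- length(d)
  dimv[2:(1 + length(d))] <- d
  dimv[dimv == 0] <- 1L
  writeBin(as.integer(dimv), con, size = 2)          # dim
  writeBin(raw(14), con)                             # intent_p*, intent_code
  writeBin(as.integer(c(dt, bitpix, 0L)), con, size = 2) # datatype,bitpix,slice_start
  sp <- sqrt(colSums(world[1:3, 1:3]^2))
  pixdim <- c(1, sp, rep(1, 4))
  writeBin(as.numeric(pixdim), con, size = 4)        # pixdim[0..7]
  writeBin(c(352, 1, 0), con, size = 4)              # vox_offset, scl_slope, scl_inter
  writeBin(raw(2 + 1 + 1), con)                      # slice_end, slice_code, xyzt_units
  writeBin(numeric(3), con, size = 4)                # cal_max, cal_min, slice_duration
  writeBin(numeric(1), con, size = 4)                # toffset
  writeBin(integer(2), con, size = 4)                # glmax, glmin
  writeBin(raw(80 + 24), con)                        # descrip, aux_file
  writeBin(as.integer(c(0L, 2L)), con, size = 2)     # qform_code=0, sform_code=2
  writeBin(numeric(6), con, size = 4)                # quatern b,c,d + qoffset x,y,z
  writeBin(as.numeric(t(world[1:3, , drop = FALSE])), con, size = 4) # srow_x/y/z
  writeBin(raw(16), con)                             # intent_name
  writeChar("n+1", con, nchars = 3, eos = NULL)
  writeBin(raw(1), con)
  writeBin(raw(4), con)                              # extension flag
  sz <- as.integer(bitpix / 8)
  if (datatype == "int32") writeBin(as.integer(vol), con, size = 4)
  else writeBin(as.numeric(vol), con, size = sz)
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Reads uncompressed `.nii` files written by [write_nifti()] (and other
#' single-file NIfTI-1 volumes using a supported datatype).
#'
#' @param path path to a `.nii` file.
#' @return list with `vol` (array), `world` (4x4 affine) and `voxel_size`.
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348)
  sz <- readBin(hdr[1:4], "integer", 1, size = 4)
  endian <- "little"
  if (sz != 348L) {
    sz <- readBin(hdr[1:4], "integer", 1, size = 4, endian = "big")
    if (sz != 348L) stop("not a NIfTI-1 file: ", path)
    endian <- "big"
  }
  rdint <- function(off, n, size)
    readBin(hdr[(off + 1):(off + n * size)], "integer", n, size = size,
            endian = endian)
  rdnum <- function(off, n, size)
    readBin(hdr[(off + 1):(off + n * size)], "double", n, size = size,
            endian = endian)
  dimv <- rdint(40, 8, 2)
  nd <- dimv[1]
  d <- dimv[2:(1 + nd)]
  dt <- rdint(70, 1, 2)
  vox_offset <- rdnum(108, 1, 4)
  srow <- matrix(rdnum(280, 12, 4), nrow = 3, byrow = TRUE)
  world <- rbind(srow, c(0, 0, 0, 1))
  n <- prod(d)
  seek(con, where = vox_offset, origin = "start")
  vol <- switch(as.character(dt),
    `2`  = readBin(con, "integer", n, size = 1, signed = FALSE, endian = endian),
    `4`  = readBin(con, "integer", n, size = 2, endian = endian),
    `8`  = readBin(con, "integer", n, size = 4, endian = endian),
    `16` = readBin(con, "double", n, size = 4, endian = endian),
    `64` = readBin(con, "double", n, size = 8, endian = endian),
    stop("unsupported NIfTI datatype code: ", dt))
  dim(vol) <- d
  list(vol = vol, world = world,
       voxel_size = sqrt(colSums(world[1:3, 1:3]^2)))
}
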