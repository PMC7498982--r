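# Minimal NIfTI-1 input/output ------------------------------------------
#
# Self-contained single-file NIfTI-1 (.nii / .nii.gz) reader and writer for
# the co-registered volumes this pipeline consumes: 3-D label, metric and
# mask grids. Only the fields the pipeline relies on are interpreted: dim,
# datatype, pixdim (voxel size) and scl_slope/scl_inter. Orientation
# metadata is written as a plain scaled identity sform and ignored on read;
# inputs are assumed co-registered, so the affine carries no information
# the pipeline uses beyond voxel size.

NIFTI_DT <- list(uint8 = 2L, int16 = 4L, int32 = 8L, float32 = 16L,
                 float64 = 64L)

#' Write a 3-D array as a NIfTI-1 volume
#'
#' @param img 3-D array. Doubles are stored as float32 (float64 if
#'   `datatype = "float64"`), integers as int32 and logicals as uint8.
#' @param path Output path; a `.gz` suffix gzip-compresses the stream.
#' @param voxel_size Numeric length 3, mm per voxel along each axis.
#' @param datatype Optional storage type override, one of
#'   `"uint8"`, `"int16"`, `"int32"`, `"float32"`, `"float64"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(img, path, voxel_size = c(1, 1, 1), datatype = NULL) {
  if (length(dim(img)) != 3L)
    stop_invariant("write_nifti() expects a 3-D array")
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop_invariant("voxel_size must be 3 positive numbers (mm)")
  if (is.null(datatype)) {
    datatype <- if (is.logical(img)) "uint8"
    else if (is.integer(img)) "int32"
    else "float32"
  }
  code <- NIFTI_DT[[datatype]]
  if (is.null(code)) stop_invariant("unsupported datatype: ", datatype)
  bitpix <- c(`2` = 8L, `4` = 16L, `8` = 32L, `16` = 32L, `64` = 64L)[
    as.character(code)]

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wb <- function(x, size) writeBin(x, con, size = size, endian = "little")
  pad <- function(n) wb(raw(n), 1L)

  wb(348L, 4L)                            # sizeof_hdr
  pad(36L)                                # unused header prelude + dim_info
  wb(as.integer(c(3L, dim(img), 1L, 1L, 1L, 1L)), 2L)  # dim[8]
  wb(numeric(3), 4L)                      # intent_p1..p3
  wb(0L, 2L)                              # intent_code
  wb(as.integer(code), 2L)                # datatype
  wb(as.integer(bitpix), 2L)              # bitpix
  wb(0L, 2L)                              # slice_start
  wb(c(1, voxel_size, 1, 1, 1, 1), 4L)    # pixdim[8] (qfac = 1)
  wb(352, 4L)                             # vox_offset
  wb(c(1, 0), 4L)                         # scl_slope, scl_inter
  wb(0L, 2L); pad(2L)                     # slice_end, slice_code, xyzt_units
  wb(numeric(4), 4L)                      # cal_max/min, slice_duration, toffset
  wb(c(0L, 0L), 4L)                       # glmax, glmin
  pad(104L)                               # descrip, aux_file
  wb(c(0L, 1L), 2L)                       # qform_code = 0, sform_code = 1
  wb(numeric(6), 4L)                      # quaternion + qoffsets
  srow <- rbind(c(voxel_size[1], 0, 0, 0),
                c(0, voxel_size[2], 0, 0),
                c(0, 0, voxel_size[3], 0))
  wb(as.numeric(t(srow)), 4L)             # srow_x/y/z
  pad(16L)                                # intent_name
  writeChar("n+1", con, nchars = 3L, eos = NULL); pad(1L)  # magic
  pad(4L)                                 # extension flag

  storage <- switch(datatype,
    uint8 = as.integer(img), int16 = as.integer(img), int32 = as.integer(img),
    as.numeric(img))
  wb(storage, bitpix %/% 8L)
  invisible(path)
}

#' Read a NIfTI-1 volume written by this package or standard tools
#'
#' Returns the image as an array with a `voxel_size` attribute (pixdim 1-3).
#' Data are returned on the scaled (`scl_slope`/`scl_inter`) scale. Both
#' endiannesses are handled; only single-frame 3-D volumes are supported.
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return Array (integer for integer storage types, double otherwise).
#' @export
read_nifti <- function(path) {
  con <- gzfile(path, "rb")   # gzfile transparently reads plain files too
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop_invariant("truncated NIfTI header in ", path)
  rd <- function(what, n, size, offset, endian) {
    readBin(hdr[(offset + 1L):length(hdr)], what, n = n, size = size,
            endian = endian, signed = !(what == "integer" && size == 1L))
  }
  endian <- "little"
  if (rd("integer", 1L, 4L, 0L, endian) != 348L) {
    endian <- "big"
    if (rd("integer", 1L, 4L, 0L, endian) != 348L)
      stop_invariant(path, " is not a NIfTI-1 file (sizeof_hdr != 348)")
  }
  dim8 <- rd("integer", 8L, 2L, 40L, endian)
  ndim <- dim8[1]
  if (ndim < 3L || any(dim8[5:8][seq_len(max(0L, ndim - 3L))] > 1L))
    stop_invariant("only single-frame 3-D volumes are supported")
  shape <- dim8[2:4]
  datatype <- rd("integer", 1L, 2L, 70L, endian)
  pixdim <- rd("numeric", 8L, 4L, 76L, endian)
  vox_offset <- rd("numeric", 1L, 4L, 108L, endian)
  scl <- rd("numeric", 2L, 4L, 112L, endian)

  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  n <- prod(shape)
  dat <- switch(as.character(datatype),
    `2` = readBin(con, "integer", n, size = 1L, signed = FALSE, endian = endian),
    `4` = readBin(con, "integer", n, size = 2L, endian = endian),
    `8` = readBin(con, "integer", n, size = 4L, endian = endian),
    `16` = readBin(con, "numeric", n, size = 4L, endian = endian),
    `64` = readBin(con, "numeric", n, size = 8L, endian = endian),
    stop_invariant("unsupported NIfTI datatype code: ", datatype))
  if (length(dat) < n) stop_invariant("truncated NIfTI data in ", path)
  if (scl[1] != 0 && !(scl[1] == 1 && scl[2] == 0))
    dat <- dat * scl[1] + scl[2]
  out <- array(dat, dim = shape)
  attr(out, "voxel_size") <- pixdim[2:4]
  out
}
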