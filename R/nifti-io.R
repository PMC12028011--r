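# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
#
# No NIfTI package ships with the supported R environment, so the small
# subset of the format this package needs is implemented here: 3-D scalar
# images, datatypes uint8/int16/int32/float32/float64, scl_slope/scl_inter
# rescaling, both endiannesses on read.  The on-disk axis order is the
# in-memory array order (slice, row, col) with pixdim (dz, dy, dx); the
# sform affine written is the diagonal spacing matrix.

NIFTI_DTYPES <- data.frame(
  code    = c(2L, 4L, 8L, 16L, 64L),
  name    = c("uint8", "int16", "int32", "float32", "float64"),
  bitpix  = c(8L, 16L, 32L, 32L, 64L),
  what    = c("integer", "integer", "integer", "double", "double"),
  signed  = c(FALSE, TRUE, TRUE, TRUE, TRUE),
  stringsAsFactors = FALSE
)

nifti_con <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Read a 3-D NIfTI-1 image
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A list with `voxels` (3-D array, axis order as stored),
#'   `spacing` (numeric length-3, mm per stored axis) and `datatype`.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  con <- nifti_con(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stopf("truncated NIfTI header in %s", path)
  endian <- "little"
  sizeof_hdr <- readBin(hdr[1:4], "integer", size = 4L, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(hdr[1:4], "integer", size = 4L, endian = endian)
    if (sizeof_hdr != 348L) stopf("%s is not a NIfTI-1 file", path)
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stopf("%s lacks a NIfTI magic string", path)
  if (magic == "ni1") stopf("two-file (.hdr/.img) NIfTI is not supported: %s", path)
  rd <- function(off, what, n, size) {
    readBin(hdr[(off + 1):(off + n * size)], what, n = n, size = size,
            endian = endian, signed = TRUE)
  }
  dim0 <- rd(40, "integer", 8, 2)
  ndim <- dim0[1]
  if (ndim < 3L) stopf("expected a 3-D image, got %d-D: %s", ndim, path)
  shape <- dim0[2:4]
  extra <- if (ndim > 3L) dim0[5:(ndim + 1)] else integer()
  if (length(extra) && any(extra > 1L))
    stopf("expected a 3-D image but %s has trailing dimensions > 1", path)
  datatype <- rd(70, "integer", 1, 2)
  row <- NIFTI_DTYPES[NIFTI_DTYPES$code == datatype, ]
  if (nrow(row) == 0) stopf("unsupported NIfTI datatype code %d in %s", datatype, path)
  pixdim <- rd(76, "double", 8, 4)
  vox_offset <- rd(108, "double", 1, 4)
  scl_slope <- rd(112, "double", 1, 4)
  scl_inter <- rd(116, "double", 1, 4)
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  nvox <- prod(shape)
  vox <- readBin(con, row$what, n = nvox, size = row$bitpix %/% 8L,
                 endian = endian, signed = row$signed)
  if (length(vox) < nvox) stopf("truncated voxel data in %s", path)
  vox <- as.double(vox)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vox <- vox * scl_slope + scl_inter
  list(voxels = array(vox, dim = shape),
       spacing = pixdim[2:4],
       datatype = row$name)
}

#' Write a 3-D array as a NIfTI-1 image
#'
#' @param voxels 3-D numeric array, axis order (slice, row, col).
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param spacing Numeric length-3 voxel spacing in mm, (dz, dy, dx).
#' @param datatype One of `"float32"`, `"float64"`, `"uint8"`, `"int16"`,
#'   `"int32"`. `float64` is lossless for R doubles.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(voxels, path, spacing, datatype = "float32") {
  if (length(dim(voxels)) != 3L) stopf("voxels must be a 3-D array")
  if (length(spacing) != 3L || any(spacing <= 0))
    stopf("spacing must be 3 strictly positive values")
  row <- NIFTI_DTYPES[NIFTI_DTYPES$name == datatype, ]
  if (nrow(row) == 0) stopf("unsupported datatype '%s'", datatype)
  shape <- dim(voxels)
  hdr <- raw(348)
  wr <- function(off, x, what, size) {
    bytes <- writeBin(x, raw(), size = size, endian = "little")
    hdr[(off + 1):(off + length(bytes))] <<- bytes
  }
  wr(0, 348L, "integer", 4)                                  # sizeof_hdr
  wr(39, as.raw(0), "raw", 1)                                # dim_info
  wr(40, as.integer(c(3L, shape, 1L, 1L, 1L, 1L)), "integer", 2)
  wr(70, row$code, "integer", 2)                             # datatype
  wr(72, row$bitpix, "integer", 2)                           # bitpix
  wr(76, c(1, spacing, 0, 0, 0, 0), "double", 4)             # pixdim
  wr(108, 352, "double", 4)                                  # vox_offset
  wr(112, 1, "double", 4)                                    # scl_slope
  wr(116, 0, "double", 4)                                    # scl_inter
  hdr[124] <- as.raw(2L)                                     # xyzt_units: mm
  wr(252, c(0L, 1L), "integer", 2)                           # qform, sform
  wr(280, c(spacing[1], 0, 0, 0), "double", 4)               # srow_x
  wr(296, c(0, spacing[2], 0, 0), "double", 4)               # srow_y
  wr(312, c(0, 0, spacing[3], 0), "double", 4)               # srow_z
  hdr[345:348] <- c(charToRaw("n+1"), as.raw(0L))            # magic
  con <- nifti_con(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(raw(4), con)                                      # no extensions
  v <- as.vector(voxels)
  if (row$what == "integer") {
    v <- as.integer(round(v))
    writeBin(v, con, size = row$bitpix %/% 8L, endian = "little")
  } else {
    writeBin(v, con, size = row$bitpix %/% 8L, endian = "little")
  }
  invisible(path)
}
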