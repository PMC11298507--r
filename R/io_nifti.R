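# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
#
# No NIfTI package is available in the target library, so the subset of the
# format this package itself needs is implemented here: little-endian
# single-file NIfTI-1 ("n+1"), datatypes uint8/int16/int32/float32/float64,
# no extensions. Integer-typed data round-trips bit-exactly.

NIFTI_DTYPES <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE, r_write = "uint8"),
  `4`  = list(what = "integer", size = 2L, signed = TRUE,  r_write = "int16"),
  `8`  = list(what = "integer", size = 4L, signed = TRUE,  r_write = "int32"),
  `16` = list(what = "double",  size = 4L, signed = TRUE,  r_write = "float32"),
  `64` = list(what = "double",  size = 8L, signed = TRUE,  r_write = "float64")
)

#' @keywords internal
nifti_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Write a volume to a NIfTI-1 file
#'
#' Axial-first volume data is stored so that the file's fastest-varying axis
#' is the in-plane column axis; reading the file back with [read_nifti()]
#' reproduces the array bit-exactly for integer datatypes.
#'
#' @param volume an [as_volume()] object or 3D array (axial axis first).
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param datatype one of `"uint8"`, `"int16"`, `"int32"`, `"float32"`,
#'   `"float64"`; the default picks `int16` for integer-valued data in range,
#'   otherwise `float32`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(volume, path, datatype = NULL) {
  v <- as_volume(volume)
  arr <- v$data
  if (is.null(datatype)) {
    intish <- all(arr == round(arr)) && all(is.finite(arr))
    datatype <- if (intish && min(arr) >= -32768 && max(arr) <= 32767) {
      "int16"
    } else {
      "float32"
    }
  }
  code <- switch(datatype, uint8 = 2L, int16 = 4L, int32 = 8L,
                 float32 = 16L, float64 = 64L,
                 abort_field("datatype", "must be one of uint8, int16, int32, float32, float64"))
  info <- NIFTI_DTYPES[[as.character(code)]]
  bitpix <- info$size * 8L

  # file axis order: (x, y, z) fastest-first; our array is (axial z, y, x)
  ax <- v$axial_axis
  perm <- c(setdiff(3:1, ax), ax)            # data axes giving (x, y, z)
  file_arr <- aperm(arr, perm)
  fdim <- dim(file_arr)
  fspacing <- v$spacing[perm]

  con <- nifti_connection(path, "wb")
  on.exit(close(con), add = TRUE)
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wd <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")

  wi(348L, 4)                                 # sizeof_hdr
  writeBin(raw(35), con)                      # data_type[10], db_name[18], extents, session_error, regular? (see below)
  # NB: the 35 raw bytes above cover data_type(10) + db_name(18) + extents(4)
  #     + session_error(2) + regular(1); dim_info follows.
  writeBin(as.raw(0L), con)                   # dim_info
  wi(c(3L, fdim, 1L, 1L, 1L, 1L), 2)          # dim[8]
  wd(c(0, 0, 0))                              # intent_p1..p3
  wi(0L, 2)                                   # intent_code
  wi(code, 2)                                 # datatype
  wi(bitpix, 2)                               # bitpix
  wi(0L, 2)                                   # slice_start
  wd(c(1, fspacing, 1, 1, 1, 1))              # pixdim[8] (qfac = 1)
  wd(352)                                     # vox_offset
  wd(c(1, 0))                                 # scl_slope, scl_inter
  wi(0L, 2)                                   # slice_end
  writeBin(raw(2), con)                       # slice_code, xyzt_units
  wd(c(0, 0, 0))                              # cal_max, cal_min, slice_duration
  wd(0)                                       # toffset
  wi(c(0L, 0L), 4)                            # glmax, glmin
  writeBin(raw(104), con)                     # descrip[80] + aux_file[24]
  wi(c(0L, 1L), 2)                            # qform_code = 0, sform_code = 1
  wd(c(0, 0, 0, 0, 0, 0))                     # quatern b,c,d + qoffset x,y,z
  wd(c(fspacing[1], 0, 0, 0))                 # srow_x
  wd(c(0, fspacing[2], 0, 0))                 # srow_y
  wd(c(0, 0, fspacing[3], 0))                 # srow_z
  writeBin(raw(16), con)                      # intent_name[16]
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)  # magic
  writeBin(raw(4), con)                       # extension flag

  vec <- as.vector(file_arr)
  if (info$what == "integer") {
    writeBin(as.integer(round(vec)), con, size = info$size, endian = "little")
  } else {
    writeBin(as.double(vec), con, size = info$size, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Supports little-endian single-file NIfTI-1 with datatypes uint8, int16,
#' int32, float32 and float64; `scl_slope`/`scl_inter` are applied when set.
#'
#' @param path a `.nii` or `.nii.gz` file.
#' @param axial_axis which axis of the returned array indexes slices
#'   (default 1: the file's z axis becomes the first array axis).
#' @return an `is_volume`.
#' @export
read_nifti <- function(path, axial_axis = 1L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- nifti_connection(path, "rb")
  on.exit(close(con), add = TRUE)
  ri <- function(n, size) readBin(con, "integer", n = n, size = size, endian = "little")
  rd <- function(n, size = 4L) readBin(con, "double", n = n, size = size, endian = "little")

  sizeof_hdr <- ri(1, 4)
  if (!identical(sizeof_hdr, 348L)) {
    stop("not a little-endian NIfTI-1 file: ", path, call. = FALSE)
  }
  readBin(con, "raw", n = 36)                 # data_type..dim_info
  dims <- ri(8, 2)
  ndim <- dims[1]
  if (ndim < 3) stop("expected a 3D NIfTI volume", call. = FALSE)
  fdim <- dims[2:4]
  if (ndim > 3 && any(dims[5:(1 + ndim)] > 1)) {
    stop("expected a 3D NIfTI volume (got >3 non-singleton dims)", call. = FALSE)
  }
  rd(3)                                       # intent_p
  ri(1, 2)                                    # intent_code
  datatype <- ri(1, 2)
  ri(1, 2); ri(1, 2)                          # bitpix, slice_start
  pixdim <- rd(8)
  vox_offset <- rd(1)
  scl_slope <- rd(1); scl_inter <- rd(1)
  info <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(info)) {
    stop("unsupported NIfTI datatype code: ", datatype, call. = FALSE)
  }
  # sequential skip (seek() is unreliable on gzfile connections); position
  # after scl_inter is byte 120, magic lives at 344
  readBin(con, "raw", n = 344 - 120)
  magic <- rawToChar(readBin(con, "raw", n = 3))
  if (!magic %in% c("n+1", "ni1")) stop("bad NIfTI magic: ", magic, call. = FALSE)
  readBin(con, "raw", n = as.integer(vox_offset) - 347L)
  nvox <- prod(fdim)
  vec <- readBin(con, info$what, n = nvox, size = info$size,
                 signed = info$signed, endian = "little")
  if (length(vec) != nvox) stop("truncated NIfTI data: ", path, call. = FALSE)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vec <- vec * scl_slope + scl_inter
  }
  file_arr <- array(as.double(vec), fdim)     # (x, y, z)
  arr <- aperm(file_arr, c(3, 2, 1))          # (z, y, x): axial first
  spacing <- pixdim[c(4, 3, 2)]
  spacing[spacing <= 0] <- 1
  v <- as_volume(arr, spacing = spacing, axial_axis = 1L)
  if (axial_axis != 1L) {
    perm <- c(axial_axis, setdiff(1:3, axial_axis))
    v <- as_volume(aperm(arr, order(perm)), spacing = spacing[order(perm)],
                   axial_axis = as.integer(axial_axis))
  }
  v
}
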