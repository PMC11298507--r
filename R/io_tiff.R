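# Minimal baseline grayscale TIFF reader and writer (little-endian,
# uncompressed, 1 sample/pixel, 8- or 16-bit). Covers the per-slice TIFF
# stacks this package exports plus plain baseline files from other writers.

TIFF_TAGS <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offsets = 273L, spp = 277L,
               rows_per_strip = 278L, strip_bytes = 279L)

#' Write a 2D image as a baseline grayscale TIFF
#'
#' @param image numeric matrix; values are rounded (half to even) to integers
#'   and must fit the chosen bit depth.
#' @param path output file path.
#' @param bits 8 or 16 bits per sample.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(image, path, bits = 16L) {
  if (!is.matrix(image)) stop("`image` must be a matrix", call. = FALSE)
  bits <- as.integer(bits)
  if (!bits %in% c(8L, 16L)) abort_field("bits", "must be 8 or 16")
  vals <- as.integer(round(as.vector(t(image))))   # row-major pixel order
  if (any(vals < 0) || any(vals > 2^bits - 1)) {
    stop(sprintf("image values outside unsigned %d-bit range", bits), call. = FALSE)
  }
  h <- nrow(image); w <- ncol(image)
  bytes_pp <- bits %/% 8L
  data_bytes <- h * w * bytes_pp
  data_offset <- 8L
  ifd_offset <- data_offset + data_bytes
  if (ifd_offset %% 2L == 1L) ifd_offset <- ifd_offset + 1L

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  w2 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")

  writeBin(charToRaw("II"), con); w2(42L); w4(ifd_offset)
  writeBin(vals, con, size = bytes_pp, endian = "little")
  if (ifd_offset > data_offset + data_bytes) writeBin(raw(1), con)

  entry <- function(tag, type, count, value) {
    w2(tag); w2(type); w4(count)
    if (type == 3L) { w2(value); w2(0L) } else w4(value)  # SHORT packs left
  }
  w2(9L)  # entry count
  entry(TIFF_TAGS[["width"]], 3L, 1L, w)
  entry(TIFF_TAGS[["length"]], 3L, 1L, h)
  entry(TIFF_TAGS[["bits"]], 3L, 1L, bits)
  entry(TIFF_TAGS[["compression"]], 3L, 1L, 1L)
  entry(TIFF_TAGS[["photometric"]], 3L, 1L, 1L)   # BlackIsZero
  entry(TIFF_TAGS[["strip_offsets"]], 4L, 1L, data_offset)
  entry(TIFF_TAGS[["spp"]], 3L, 1L, 1L)
  entry(TIFF_TAGS[["rows_per_strip"]], 3L, 1L, h)
  entry(TIFF_TAGS[["strip_bytes"]], 4L, 1L, data_bytes)
  w4(0L)  # next IFD
  invisible(path)
}

#' Read a baseline grayscale TIFF
#'
#' Supports little-endian, uncompressed, single-sample images with 8 or 16
#' bits per sample (one or more strips, first image/page only).
#'
#' @param path TIFF file path.
#' @return numeric matrix (rows = image rows).
#' @export
read_tiff <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw_all <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw_all) < 8) stop("not a TIFF file: ", path, call. = FALSE)
  order_tag <- rawToChar(raw_all[1:2])
  if (order_tag != "II") {
    stop("only little-endian ('II') TIFF files are supported", call. = FALSE)
  }
  u <- function(idx) as.numeric(raw_all[idx])  # unsigned bytes
  rd16 <- function(off) u(off + 1L) + 256 * u(off + 2L)
  rd32 <- function(off) u(off + 1L) + 256 * (u(off + 2L) + 256 * (u(off + 3L) + 256 * u(off + 4L)))
  if (rd16(2L) != 42) stop("bad TIFF magic in ", path, call. = FALSE)
  ifd <- rd32(4L)
  n_entries <- rd16(ifd)
  tags <- list()
  for (i in seq_len(n_entries)) {
    e <- ifd + 2L + (i - 1L) * 12L
    tag <- rd16(e); type <- rd16(e + 2L); count <- rd32(e + 4L)
    value <- if (type == 3L && count == 1L) rd16(e + 8L) else rd32(e + 8L)
    values <- if (count > 1L) {
      voff <- rd32(e + 8L)
      step <- if (type == 3L) 2L else 4L
      rdv <- if (type == 3L) rd16 else rd32
      vapply(seq_len(count) - 1L, function(k) rdv(voff + k * step), numeric(1))
    } else value
    tags[[as.character(tag)]] <- values
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(TIFF_TAGS[[tag]])]]
    if (is.null(v)) {
      if (is.null(default)) stop("TIFF missing required tag: ", tag, call. = FALSE)
      default
    } else v
  }
  w <- need("width"); h <- need("length")
  bits <- need("bits", 8); comp <- need("compression", 1)
  spp <- need("spp", 1)
  if (comp != 1) stop("only uncompressed TIFF is supported", call. = FALSE)
  if (spp != 1 || !bits[1] %in% c(8, 16)) {
    stop("only 8/16-bit single-sample grayscale TIFF is supported", call. = FALSE)
  }
  offsets <- need("strip_offsets"); byte_counts <- need("strip_bytes")
  bytes_pp <- bits[1] / 8
  vals <- numeric(0)
  for (s in seq_along(offsets)) {
    seg <- raw_all[(offsets[s] + 1L):(offsets[s] + byte_counts[s])]
    v <- as.numeric(seg)
    if (bytes_pp == 2) {
      v <- v[seq(1, length(v), 2)] + 256 * v[seq(2, length(v), 2)]
    }
    vals <- c(vals, v)
  }
  if (length(vals) != w * h) stop("TIFF pixel data size mismatch", call. = FALSE)
  t(matrix(vals, nrow = w, ncol = h))  # row-major file order -> (h, w) matrix
}

#' Write a volume as a per-slice TIFF stack
#'
#' One file per axial slice, named `<prefix>_s%04d.tif` so lexicographic
#' order equals slice order.
#'
#' @param volume an [as_volume()] object or 3D array; values must be
#'   non-negative integers within the bit depth.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @param bits 8 or 16.
#' @return character vector of file paths, invisibly.
#' @export
write_tiff_stack <- function(volume, dir, prefix = "slice", bits = 16L) {
  v <- as_volume(volume)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  slices <- extract_slices(v)
  paths <- file.path(dir, sprintf("%s_s%04d.tif", prefix, seq_along(slices)))
  for (k in seq_along(slices)) write_tiff(slices[[k]], paths[k], bits = bits)
  invisible(paths)
}

#' Read a TIFF stack as a volume
#'
#' @param paths either a directory (all `.tif`/`.tiff` files, sorted) or an
#'   ordered character vector of file paths.
#' @param spacing voxel spacing metadata for the resulting volume.
#' @return an `is_volume` with the axial axis first.
#' @export
read_tiff_stack <- function(paths, spacing = c(1, 1, 1)) {
  if (length(paths) == 1L && dir.exists(paths)) {
    paths <- sort(list.files(paths, pattern = "\\.tiff?$", full.names = TRUE))
  }
  if (!length(paths)) stop("no TIFF files found", call. = FALSE)
  slices <- lapply(paths, read_tiff)
  v <- stack_slices(slices)
  as_volume(v$data, spacing = spacing, axial_axis = 1L, dtype_note = "raw")
}
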