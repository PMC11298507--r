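# The core algorithm: up-sample a slice at an integer interpolation ratio
# (bilinear for images, nearest neighbour for masks), split into fixed-size
# tiles, and invert the process (merge tiles, nearest-neighbour down-sample)
# at prediction time.
#
# One grid convention is shared by all four resampling directions: output
# pixel `o` (0-based) samples source coordinate `(o + 0.5) / ir - 0.5`, with
# edge clamping, and nearest-neighbour ties resolved toward the smaller
# index. A single convention is what makes the mask round trip
# `downsample_nn(upsample_mask(m, ir), ir) == m` provable.

#' Interpolation/split configuration
#'
#' @param ir integer interpolation ratio (>= 1). `ir = 1` performs no
#'   interpolation and no split.
#' @param tile_size tile side length in pixels (>= 8). The production
#'   default is 512; desk-scale tests use 64.
#' @return an `interp_config` list.
#' @export
interp_config <- function(ir = 1L, tile_size = 512L) {
  check_scalar_number(ir, "ir", lower = 1, integer = TRUE)
  check_scalar_number(tile_size, "tile_size", lower = 8, integer = TRUE)
  structure(list(ir = as.integer(ir), tile_size = as.integer(tile_size),
                 image_interp = "bilinear", mask_interp = "nearest"),
            class = "interp_config")
}

# source-coordinate lookup shared by bilinear and NN resampling
#' @keywords internal
src_coord <- function(n_out, scale, n_src) {
  clamp(((seq_len(n_out) - 1) + 0.5) / scale - 0.5, 0, n_src - 1)
}

#' Bilinear up-sampling of a 2D image
#'
#' Output dimensions are exactly `ir` times the input dimensions. `ir = 1` is
#' the bit-exact identity. Values never leave `[min(input), max(input)]`
#' (convex weights), and any affine-in-position image is reproduced exactly
#' away from the clamped one-pixel border band.
#'
#' @param slice 2D numeric matrix.
#' @param ir integer interpolation ratio (>= 1).
#' @return matrix of dimensions `dim(slice) * ir`.
#' @export
upsample_image <- function(slice, ir) {
  if (!is.matrix(slice)) stop("`slice` must be a matrix", call. = FALSE)
  check_scalar_number(ir, "ir", lower = 1, integer = TRUE)
  ir <- as.integer(ir)
  if (ir == 1L) return(slice)
  h <- nrow(slice); w <- ncol(slice)
  sr <- src_coord(h * ir, ir, h)
  sc <- src_coord(w * ir, ir, w)
  r0 <- pmin(floor(sr), h - 1); r1 <- pmin(r0 + 1, h - 1); wr <- sr - r0
  c0 <- pmin(floor(sc), w - 1); c1 <- pmin(c0 + 1, w - 1); wc <- sc - c0
  i00 <- slice[r0 + 1, c0 + 1, drop = FALSE]
  i10 <- slice[r1 + 1, c0 + 1, drop = FALSE]
  i01 <- slice[r0 + 1, c1 + 1, drop = FALSE]
  i11 <- slice[r1 + 1, c1 + 1, drop = FALSE]
  W00 <- outer(1 - wr, 1 - wc); W10 <- outer(wr, 1 - wc)
  W01 <- outer(1 - wr, wc);     W11 <- outer(wr, wc)
  W00 * i00 + W10 * i10 + W01 * i01 + W11 * i11
}

#' Nearest-neighbour up-sampling of a binary mask
#'
#' Each output pixel copies its nearest source pixel under the same grid
#' convention as [upsample_image()]; for integer `ir` this replicates every
#' source pixel into an `ir` x `ir` block, so foreground counts multiply
#' exactly by `ir^2`.
#'
#' @param mask 2D binary matrix (values 0/1).
#' @param ir integer interpolation ratio (>= 1).
#' @return binary matrix of dimensions `dim(mask) * ir`.
#' @export
upsample_mask <- function(mask, ir) {
  if (!is.matrix(mask)) stop("`mask` must be a matrix", call. = FALSE)
  if (!all(mask %in% c(0, 1))) {
    stop("`mask` must be binary (0/1); see binarize_mask()", call. = FALSE)
  }
  check_scalar_number(ir, "ir", lower = 1, integer = TRUE)
  ir <- as.integer(ir)
  if (ir == 1L) return(mask)
  ri <- nn_index0(src_coord(nrow(mask) * ir, ir, nrow(mask)), nrow(mask))
  ci <- nn_index0(src_coord(ncol(mask) * ir, ir, ncol(mask)), ncol(mask))
  mask[ri + 1, ci + 1, drop = FALSE]
}

#' Tile grid bookkeeping for one interpolated slice
#'
#' Records everything needed for a lossless merge: the ratio, tile size,
#' row/column tile counts (row-major ordering), the interpolated canvas shape
#' and the edge-replicate padded shape.
#'
#' @param canvas_shape dimensions (rows, cols) of the interpolated slice.
#' @param tile_size tile side length.
#' @param ir interpolation ratio that produced the canvas (metadata).
#' @return a `tile_grid` list with fields `ir`, `tile_size`, `n_rows`,
#'   `n_cols`, `source_shape`, `canvas_shape`, `padded_shape`, `ordering`.
#' @export
tile_grid <- function(canvas_shape, tile_size, ir = 1L) {
  check_scalar_number(tile_size, "tile_size", lower = 8, integer = TRUE)
  check_scalar_number(ir, "ir", lower = 1, integer = TRUE)
  if (any(canvas_shape < 1)) stop("canvas must be at least 1 x 1", call. = FALSE)
  n_rows <- as.integer(ceiling(canvas_shape[1] / tile_size))
  n_cols <- as.integer(ceiling(canvas_shape[2] / tile_size))
  structure(
    list(ir = as.integer(ir), tile_size = as.integer(tile_size),
         n_rows = n_rows, n_cols = n_cols,
         source_shape = as.integer(canvas_shape / ir),
         canvas_shape = as.integer(canvas_shape),
         padded_shape = c(n_rows, n_cols) * as.integer(tile_size),
         ordering = "row-major"),
    class = "tile_grid"
  )
}

#' Split a canvas into non-overlapping fixed-size tiles
#'
#' Row-major order. If the canvas dimensions are not multiples of the tile
#' size, the canvas is edge-replicate padded up to the next multiple;
#' [merge_tiles()] crops the padding back off.
#'
#' @param image 2D numeric matrix (the interpolated canvas).
#' @param tile_size tile side length (>= 8).
#' @param ir ratio metadata recorded in the grid.
#' @param slice_index provenance: which axial slice this canvas came from.
#' @return a `tile_set`: list with `tiles` (list of `tile_size` x
#'   `tile_size` matrices), `grid` (a [tile_grid()]) and `slice_index`.
#' @export
split_tiles <- function(image, tile_size, ir = 1L, slice_index = NA_integer_) {
  if (!is.matrix(image) || any(dim(image) < 1)) {
    stop("`image` must be a matrix of at least 1 x 1", call. = FALSE)
  }
  grid <- tile_grid(dim(image), tile_size, ir)
  tsz <- grid$tile_size
  pad <- grid$padded_shape
  ridx <- clamp(seq_len(pad[1]), 1, nrow(image))
  cidx <- clamp(seq_len(pad[2]), 1, ncol(image))
  canvas <- image[ridx, cidx, drop = FALSE]
  tiles <- vector("list", grid$n_rows * grid$n_cols)
  k <- 0L
  for (r in seq_len(grid$n_rows)) {
    for (cc in seq_len(grid$n_cols)) {
      k <- k + 1L
      tiles[[k]] <- canvas[((r - 1L) * tsz + 1L):(r * tsz),
                           ((cc - 1L) * tsz + 1L):(cc * tsz), drop = FALSE]
    }
  }
  structure(list(tiles = tiles, grid = grid, slice_index = slice_index),
            class = "tile_set")
}

#' Merge a tile set back into its canvas
#'
#' Reassembles the padded canvas in row-major order, then crops any padding,
#' so `merge_tiles(split_tiles(x, T))` is bit-exactly `x`.
#'
#' @param tileset a `tile_set` from [split_tiles()] (or with the same
#'   structure, e.g. after per-tile prediction).
#' @return 2D matrix with the grid's canvas dimensions.
#' @export
merge_tiles <- function(tileset) {
  grid <- tileset$grid
  tsz <- grid$tile_size
  if (length(tileset$tiles) != grid$n_rows * grid$n_cols) {
    stop(sprintf("tile count %d does not match grid %d x %d",
                 length(tileset$tiles), grid$n_rows, grid$n_cols), call. = FALSE)
  }
  canvas <- matrix(0, grid$padded_shape[1], grid$padded_shape[2])
  k <- 0L
  for (r in seq_len(grid$n_rows)) {
    for (cc in seq_len(grid$n_cols)) {
      k <- k + 1L
      tile <- tileset$tiles[[k]]
      if (!identical(dim(tile), c(tsz, tsz))) {
        stop(sprintf("tile %d is %s, expected %d x %d", k,
                     paste(dim(tile), collapse = " x "), tsz, tsz), call. = FALSE)
      }
      canvas[((r - 1L) * tsz + 1L):(r * tsz),
             ((cc - 1L) * tsz + 1L):(cc * tsz)] <- tile
    }
  }
  canvas[seq_len(grid$canvas_shape[1]), seq_len(grid$canvas_shape[2]), drop = FALSE]
}

#' Closed-form tile count for one slice
#'
#' `ceil(height * ir / T) * ceil(width * ir / T)`; for 512 x 512 slices with
#' `T = 512` this is `ir^2` (4 tiles at ir = 2, 64 at ir = 8).
#'
#' @param height,width source slice dimensions in pixels.
#' @param ir interpolation ratio.
#' @param tile_size tile side length.
#' @return integer tile count.
#' @export
count_tiles <- function(height, width, ir, tile_size = 512L) {
  check_scalar_number(height, "height", lower = 1)
  check_scalar_number(width, "width", lower = 1)
  check_scalar_number(ir, "ir", lower = 1, integer = TRUE)
  check_scalar_number(tile_size, "tile_size", lower = 1, integer = TRUE)
  as.integer(ceiling(height * ir / tile_size) * ceiling(width * ir / tile_size))
}

#' Total tile count over a dataset and a set of interpolation ratios
#'
#' For 512 x 512 slices with T = 512 this equals
#' `n_slices * sum(ir^2)`: e.g. 7552 slices over ratios {1, 2, 4, 8} give
#' 7552 * 85 = 641,920 training samples.
#'
#' @param n_slices number of source slices (>= 0).
#' @param irs vector of interpolation ratios.
#' @param slice_shape source slice dimensions (default `c(512, 512)`).
#' @param tile_size tile side length (default 512).
#' @return total tile count as a double (counts can exceed .Machine$integer.max).
#' @export
count_dataset_tiles <- function(n_slices, irs, slice_shape = c(512, 512),
                                tile_size = 512L) {
  check_scalar_number(n_slices, "n_slices", lower = 0, integer = TRUE)
  per_slice <- vapply(irs, function(ir) {
    as.numeric(count_tiles(slice_shape[1], slice_shape[2], ir, tile_size))
  }, numeric(1))
  n_slices * sum(per_slice)
}

#' Nearest-neighbour down-sampling
#'
#' Inverse of the up-sampling step under the shared grid convention:
#' `downsample_nn(upsample_mask(m, ir), ir)` is bit-exactly `m`.
#'
#' @param canvas 2D matrix whose dimensions are divisible by `ir`.
#' @param ir integer ratio (>= 1).
#' @return matrix of dimensions `dim(canvas) / ir`.
#' @export
downsample_nn <- function(canvas, ir) {
  if (!is.matrix(canvas)) stop("`canvas` must be a matrix", call. = FALSE)
  check_scalar_number(ir, "ir", lower = 1, integer = TRUE)
  ir <- as.integer(ir)
  if (ir == 1L) return(canvas)
  if (any(dim(canvas) %% ir != 0)) {
    stop(sprintf("canvas dimensions %s are not divisible by ir = %d",
                 paste(dim(canvas), collapse = " x "), ir), call. = FALSE)
  }
  h <- nrow(canvas) %/% ir; w <- ncol(canvas) %/% ir
  ri <- nn_index0(((seq_len(h) - 1) + 0.5) * ir - 0.5, nrow(canvas))
  ci <- nn_index0(((seq_len(w) - 1) + 0.5) * ir - 0.5, ncol(canvas))
  canvas[ri + 1, ci + 1, drop = FALSE]
}

#' Build aligned image/mask tile pairs for training
#'
#' The image path uses bilinear up-sampling, the mask path nearest neighbour;
#' both are split with the same tile grid, so pairs align by tile index.
#'
#' @param slice 2D image matrix.
#' @param mask 2D binary matrix of the same dimensions.
#' @param config an [interp_config()].
#' @param slice_index provenance.
#' @return list of pairs, each `list(image, mask, row, col, slice_index)`.
#' @export
prepare_pair <- function(slice, mask, config, slice_index = NA_integer_) {
  if (!identical(dim(slice), dim(mask))) {
    stop("slice and mask dimensions differ", call. = FALSE)
  }
  img_tiles <- split_tiles(upsample_image(slice, config$ir), config$tile_size,
                           ir = config$ir, slice_index = slice_index)
  msk_tiles <- split_tiles(upsample_mask(mask, config$ir), config$tile_size,
                           ir = config$ir, slice_index = slice_index)
  g <- img_tiles$grid
  out <- vector("list", length(img_tiles$tiles))
  for (k in seq_along(out)) {
    r <- (k - 1L) %/% g$n_cols
    cc <- (k - 1L) %% g$n_cols
    out[[k]] <- list(image = img_tiles$tiles[[k]], mask = msk_tiles$tiles[[k]],
                     row = r, col = cc, slice_index = slice_index)
  }
  out
}

#' Reconstruct a source-resolution prediction from predicted tiles
#'
#' [merge_tiles()] followed by [downsample_nn()]; the output lives at the
#' original slice dimensions with values in `[0, 1]`.
#'
#' @param pred_tiles a `tile_set` of probability-map tiles in `[0, 1]`.
#' @param ir the interpolation ratio that produced the tiles.
#' @return 2D probability matrix at source resolution.
#' @export
reconstruct_prediction <- function(pred_tiles, ir) {
  vals <- unlist(pred_tiles$tiles, use.names = FALSE)
  if (min(vals) < 0 || max(vals) > 1) {
    stop("prediction tiles must lie in [0, 1]", call. = FALSE)
  }
  downsample_nn(merge_tiles(pred_tiles), ir)
}

#' Export a tile set as TIFF files plus a JSON grid manifest
#'
#' Files are named `slice{k}_r{r}_c{c}.tif` so the merge is independent of
#' filesystem listing order; the manifest records the grid and file names.
#'
#' @param tileset a `tile_set`.
#' @param dir output directory.
#' @param bits TIFF bit depth (values must be non-negative integers in range).
#' @return the manifest path, invisibly.
#' @export
export_tiles <- function(tileset, dir, bits = 16L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- tileset$grid
  k <- 0L
  files <- character(length(tileset$tiles))
  for (r in seq_len(g$n_rows) - 1L) {
    for (cc in seq_len(g$n_cols) - 1L) {
      k <- k + 1L
      files[k] <- sprintf("slice%d_r%d_c%d.tif",
                          ifelse(is.na(tileset$slice_index), 0L, tileset$slice_index),
                          r, cc)
      write_tiff(tileset$tiles[[k]], file.path(dir, files[k]), bits = bits)
    }
  }
  manifest <- file.path(dir, "grid.json")
  jsonlite::write_json(list(grid = unclass(g), slice_index = tileset$slice_index,
                            files = files),
                       manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Import a tile set written by [export_tiles()]
#'
#' @param manifest path to the `grid.json` manifest.
#' @return a `tile_set`.
#' @export
import_tiles <- function(manifest) {
  meta <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  g <- meta$grid
  grid <- tile_grid(g$canvas_shape, g$tile_size, g$ir)
  tiles <- lapply(file.path(dirname(manifest), meta$files), read_tiff)
  structure(list(tiles = tiles, grid = grid,
                 slice_index = if (is.null(meta$slice_index)) NA_integer_ else meta$slice_index),
            class = "tile_set")
}
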