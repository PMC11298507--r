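# Bilinear-interpolation mathematical model and artefact analyses: the
# closed-form four-corner interpolant, the crop-then-upscale comparator
# ("existing technique"), seam-discontinuity statistics and the
# diagonal-Laplacian sharpness study.

#' A bilinear interpolation cell
#'
#' Four known corner samples on an axis-aligned rectangle:
#' `f11` at (x1, y1), `f21` at (x2, y1), `f12` at (x1, y2), `f22` at (x2, y2).
#'
#' @param f11,f21,f12,f22 corner intensities.
#' @param x1,x2,y1,y2 corner coordinates with `x1 < x2`, `y1 < y2`.
#' @return a `bilinear_cell` list.
#' @export
bilinear_cell <- function(f11, f21, f12, f22, x1 = 0, x2 = 1, y1 = 0, y2 = 1) {
  if (!(x1 < x2) || !(y1 < y2)) {
    stop("degenerate cell: need x1 < x2 and y1 < y2", call. = FALSE)
  }
  structure(list(f11 = f11, f21 = f21, f12 = f12, f22 = f22,
                 x1 = x1, x2 = x2, y1 = y1, y2 = y2),
            class = "bilinear_cell")
}

#' Evaluate the bilinear interpolant at a query point
#'
#' Linear interpolation along x at each of the two rows, giving the
#' intermediate values `f(C1) = f(x, y1)` and `f(C2) = f(x, y2)`, followed by
#' linear interpolation along y between them. Exact at the corners, linear
#' along each edge, and reproduces any affine function of position exactly.
#'
#' @param cell a [bilinear_cell()].
#' @param x,y query coordinates inside the cell (vectorised).
#' @return interpolated intensity value(s).
#' @examples
#' bilinear_point(bilinear_cell(0, 1, 2, 3), 0.5, 0.5)  # 1.5
#' @export
bilinear_point <- function(cell, x, y) {
  if (!inherits(cell, "bilinear_cell")) {
    stop("`cell` must be a bilinear_cell", call. = FALSE)
  }
  if (any(x < cell$x1 - 1e-12) || any(x > cell$x2 + 1e-12) ||
      any(y < cell$y1 - 1e-12) || any(y > cell$y2 + 1e-12)) {
    stop("query point outside the cell", call. = FALSE)
  }
  dx <- cell$x2 - cell$x1
  dy <- cell$y2 - cell$y1
  fc1 <- (cell$x2 - x) / dx * cell$f11 + (x - cell$x1) / dx * cell$f21
  fc2 <- (cell$x2 - x) / dx * cell$f12 + (x - cell$x1) / dx * cell$f22
  (cell$y2 - y) / dy * fc1 + (y - cell$y1) / dy * fc2
}

#' Crop-then-upscale comparator (the "existing technique")
#'
#' Partition the image into `block` x `block` crops, bilinearly up-scale each
#' crop by `ir` independently (each with its own clamped edges), and
#' reassemble in place. Per-block edge clamping is precisely what creates
#' seam discontinuities and the blur/edge artefacts the interpolation-split
#' pipeline avoids by up-scaling the whole image before splitting.
#'
#' @param image 2D matrix whose dimensions are divisible by `block`.
#' @param block crop side length.
#' @param ir integer up-scaling ratio.
#' @return matrix of dimensions `dim(image) * ir`.
#' @export
crop_then_upscale <- function(image, block, ir) {
  if (!is.matrix(image)) stop("`image` must be a matrix", call. = FALSE)
  check_scalar_number(block, "block", lower = 1, integer = TRUE)
  check_scalar_number(ir, "ir", lower = 1, integer = TRUE)
  if (any(dim(image) %% block != 0)) {
    stop(sprintf("image dimensions %s are not divisible by block = %d",
                 paste(dim(image), collapse = " x "), block), call. = FALSE)
  }
  ir <- as.integer(ir); block <- as.integer(block)
  if (ir == 1L) return(image)
  out <- matrix(0, nrow(image) * ir, ncol(image) * ir)
  bo <- block * ir
  for (br in seq_len(nrow(image) %/% block) - 1L) {
    for (bc in seq_len(ncol(image) %/% block) - 1L) {
      crop <- image[br * block + seq_len(block), bc * block + seq_len(block),
                    drop = FALSE]
      out[br * bo + seq_len(bo), bc * bo + seq_len(bo)] <- upsample_image(crop, ir)
    }
  }
  out
}

#' Extract a row or column intensity profile
#'
#' @param canvas 2D matrix.
#' @param axis `"row"` or `"column"`.
#' @param index 1-based row/column index.
#' @return numeric vector (the selected row or column, unchanged).
#' @export
intensity_profile <- function(canvas, axis = c("row", "column"), index) {
  axis <- match.arg(axis)
  n <- if (axis == "row") nrow(canvas) else ncol(canvas)
  check_scalar_number(index, "index", lower = 1, upper = n, integer = TRUE)
  if (axis == "row") canvas[index, ] else canvas[, index]
}

# positions (1-based, first column/row of the right/lower tile) of the
# internal seams of a tile grid
#' @keywords internal
grid_seams <- function(grid) {
  tsz <- grid$tile_size
  list(rows = if (grid$n_rows > 1) tsz * seq_len(grid$n_rows - 1) + 1 else integer(0),
       cols = if (grid$n_cols > 1) tsz * seq_len(grid$n_cols - 1) + 1 else integer(0))
}

#' Seam-discontinuity statistic
#'
#' Formalises the intensity jump at tile boundaries: `seam_step` is the mean
#' absolute adjacent-pixel difference across seam pairs (rows and columns
#' pooled), `interior_step` the same statistic over all non-seam adjacent
#' pairs, and `discontinuity = seam_step - interior_step`. A difference (not
#' a ratio) keeps the statistic defined on constant images.
#'
#' `margin` excludes that many pixels at each canvas border from both means:
#' edge-clamped half-pixel-centre resampling flattens the outermost pixel
#' pairs of any up-sampled image, which is a border effect, not a seam
#' effect. Pass `margin = floor(ir / 2)` when the canvas was up-sampled by
#' `ir` (the clamped band has exactly that width).
#'
#' @param canvas 2D matrix.
#' @param seams either a [tile_grid()] or a list with integer vectors `rows`
#'   and/or `cols`: 1-based indices of the first row/column *after* each seam.
#' @param margin border width excluded from the statistic (default 0).
#' @return a `seam_report`: list with `seam_step`, `interior_step`,
#'   `discontinuity`.
#' @export
seam_discontinuity <- function(canvas, seams, margin = 0L) {
  if (!is.matrix(canvas)) stop("`canvas` must be a matrix", call. = FALSE)
  if (inherits(seams, "tile_grid")) seams <- grid_seams(seams)
  seam_rows <- as.integer(seams$rows %||% integer(0))
  seam_cols <- as.integer(seams$cols %||% integer(0))
  h <- nrow(canvas); w <- ncol(canvas)
  m <- as.integer(margin)
  ok_rows <- seam_rows[seam_rows > 1 + m & seam_rows <= h - m]
  ok_cols <- seam_cols[seam_cols > 1 + m & seam_cols <= w - m]
  if (!length(ok_rows) && !length(ok_cols)) {
    stop("no seam position strictly inside the canvas", call. = FALSE)
  }
  seam_vals <- c(); int_vals <- c()
  cols_keep <- (1 + m):(w - m)
  rows_keep <- (1 + m):(h - m)
  # vertical pairs (r-1, r): candidate boundary rows r
  cand_r <- rows_keep[rows_keep >= 2 + m]
  if (length(cand_r)) {
    dr <- abs(canvas[cand_r, cols_keep, drop = FALSE] -
                canvas[cand_r - 1, cols_keep, drop = FALSE])
    at_seam <- cand_r %in% ok_rows
    seam_vals <- c(seam_vals, as.vector(dr[at_seam, , drop = FALSE]))
    int_vals <- c(int_vals, as.vector(dr[!at_seam, , drop = FALSE]))
  }
  cand_c <- cols_keep[cols_keep >= 2 + m]
  if (length(cand_c)) {
    dc <- abs(canvas[rows_keep, cand_c, drop = FALSE] -
                canvas[rows_keep, cand_c - 1, drop = FALSE])
    at_seam <- cand_c %in% ok_cols
    seam_vals <- c(seam_vals, as.vector(dc[, at_seam, drop = FALSE]))
    int_vals <- c(int_vals, as.vector(dc[, !at_seam, drop = FALSE]))
  }
  seam_step <- if (length(seam_vals)) mean(seam_vals) else 0
  interior_step <- if (length(int_vals)) mean(int_vals) else 0
  structure(list(seam_step = seam_step, interior_step = interior_step,
                 discontinuity = seam_step - interior_step),
            class = "seam_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Diagonal-Laplacian sharpness (focus measure)
#'
#' Mean over interior pixels of the two absolute pure-diagonal second
#' differences:
#' `|2 I(r,c) - I(r-1,c-1) - I(r+1,c+1)| + |2 I(r,c) - I(r-1,c+1) - I(r+1,c-1)|`.
#' Zero iff both diagonal second differences vanish everywhere (e.g. any
#' affine image); translation-invariant; scales linearly with contrast.
#'
#' @param image 2D matrix, at least 3 x 3.
#' @return non-negative scalar.
#' @export
diagonal_laplacian_sharpness <- function(image) {
  if (!is.matrix(image) || nrow(image) < 3 || ncol(image) < 3) {
    stop("`image` must be at least 3 x 3", call. = FALSE)
  }
  h <- nrow(image); w <- ncol(image)
  ctr <- image[2:(h - 1), 2:(w - 1), drop = FALSE]
  d1 <- abs(2 * ctr - image[1:(h - 2), 1:(w - 2), drop = FALSE] -
              image[3:h, 3:w, drop = FALSE])
  d2 <- abs(2 * ctr - image[1:(h - 2), 3:w, drop = FALSE] -
              image[3:h, 1:(w - 2), drop = FALSE])
  mean(d1 + d2)
}

#' Paired sharpness study of existing vs interpolation-split tiles
#'
#' Computes the per-tile diagonal-Laplacian sharpness for both arms, the
#' paired differences (interpolation-split minus existing), the paired
#' t statistic `mean(d) / (sd(d) / sqrt(n))` and a two-sided p-value from the
#' t distribution with `n - 1` degrees of freedom. Degenerate cases: if all
#' differences are zero the statistic is undefined (`t = NA`,
#' `degenerate = TRUE`); if the differences are constant and nonzero the
#' statistic is infinite with `p = 0`.
#'
#' @param existing list of matrices from [crop_then_upscale()] tiles.
#' @param interp_split list of matrices from whole-image up-sampling tiles,
#'   paired elementwise with `existing`.
#' @return a `sharpness_study`: per-arm sharpness vectors, means, SDs, the
#'   paired differences, `t`, `df`, `p_value`, `degenerate`.
#' @export
paired_sharpness_study <- function(existing, interp_split) {
  if (length(existing) != length(interp_split) || length(existing) < 2) {
    stop("need >= 2 pairs of sub-images", call. = FALSE)
  }
  s_exist <- vapply(existing, diagonal_laplacian_sharpness, numeric(1))
  s_split <- vapply(interp_split, diagonal_laplacian_sharpness, numeric(1))
  d <- s_split - s_exist
  n <- length(d)
  sd_d <- stats::sd(d)
  degenerate <- FALSE
  if (sd_d == 0 && mean(d) == 0) {
    t_stat <- NA_real_; p <- NA_real_; degenerate <- TRUE
  } else if (sd_d == 0) {
    t_stat <- sign(mean(d)) * Inf; p <- 0
  } else {
    t_stat <- mean(d) / (sd_d / sqrt(n))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  }
  structure(
    list(sharpness_existing = s_exist, sharpness_interp_split = s_split,
         mean_existing = mean(s_exist), mean_interp_split = mean(s_split),
         sd_existing = stats::sd(s_exist), sd_interp_split = stats::sd(s_split),
         differences = d, t = t_stat, df = as.integer(n - 1), p_value = p,
         degenerate = degenerate),
    class = "sharpness_study"
  )
}

#' @export
print.sharpness_study <- function(x, ...) {
  cat(sprintf(
    "<sharpness_study> n = %d pairs\n  existing:            %.4f +/- %.4f\n  interpolation-split: %.4f +/- %.4f\n  paired t = %s (df = %d), two-sided p = %s%s\n",
    length(x$differences), x$mean_existing, x$sd_existing,
    x$mean_interp_split, x$sd_interp_split,
    format(x$t), x$df, format.pval(x$p_value),
    if (x$degenerate) " [degenerate: all differences zero]" else ""))
  invisible(x)
}
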