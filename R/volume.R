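#' Volume: a 3D intensity grid with spacing and an axial slicing convention
#'
#' The unit every pipeline run consumes and produces. The axial axis (the one
#' that indexes 2D slices) defaults to the first array dimension, so
#' `data[k, , ]` is slice `k`; this is overridable per volume.
#'
#' @param data 3D numeric array.
#' @param spacing voxel spacing in mm per axis (length 3, all > 0).
#' @param axial_axis which array dimension indexes axial slices (1, 2 or 3).
#' @param dtype_note free-text note on the intensity scale, e.g. `"HU"` or
#'   `"normalized-0-255"`.
#' @return an object of class `is_volume`.
#' @examples
#' v <- as_volume(array(0, c(4, 8, 8)))
#' dim(v$data)
#' @export
as_volume <- function(data, spacing = c(1, 1, 1), axial_axis = 1L,
                      dtype_note = "HU") {
  if (inherits(data, "is_volume")) return(data)
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort_field("data", "must be a 3D array")
  }
  if (!is.numeric(spacing) || length(spacing) != 3L || any(spacing <= 0)) {
    abort_field("spacing", "must be 3 positive numbers (mm)")
  }
  axial_axis <- as.integer(axial_axis)
  if (!axial_axis %in% 1:3) abort_field("axial_axis", "must be 1, 2 or 3")
  structure(
    list(data = data, spacing = as.numeric(spacing), axial_axis = axial_axis,
         dtype_note = dtype_note),
    class = "is_volume"
  )
}

#' @export
print.is_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<is_volume> %d x %d x %d (axial axis %d), spacing %s mm, %s\n",
              d[1], d[2], d[3], x$axial_axis,
              paste(signif(x$spacing, 4), collapse = " x "), x$dtype_note))
  invisible(x)
}

#' @keywords internal
volume_data <- function(x) if (inherits(x, "is_volume")) x$data else x

#' Extract ordered axial slices from a volume
#'
#' One 2D matrix per axial index, in ascending order; [stack_slices()] is the
#' exact inverse.
#'
#' @param volume an [as_volume()] object or 3D array.
#' @return list of 2D matrices.
#' @export
extract_slices <- function(volume) {
  v <- as_volume(volume)
  ax <- v$axial_axis
  d <- dim(v$data)
  lapply(seq_len(d[ax]), function(k) {
    sl <- switch(ax,
                 v$data[k, , , drop = FALSE],
                 v$data[, k, , drop = FALSE],
                 v$data[, , k, drop = FALSE])
    matrix(sl, nrow = dim(sl)[setdiff(1:3, ax)][1])
  })
}

#' Stack 2D slices back into a volume
#'
#' @param slices list of equally sized matrices (as from [extract_slices()]).
#' @param template optional volume providing spacing/axial axis metadata.
#' @return an `is_volume`.
#' @export
stack_slices <- function(slices, template = NULL) {
  if (!length(slices)) stop("`slices` must be non-empty", call. = FALSE)
  ax <- if (is.null(template)) 1L else as_volume(template)$axial_axis
  d2 <- dim(slices[[1]])
  arr <- array(0, c(length(slices), d2))
  for (k in seq_along(slices)) {
    if (!identical(dim(slices[[k]]), d2)) {
      stop("all slices must have identical dimensions", call. = FALSE)
    }
    arr[k, , ] <- slices[[k]]
  }
  if (ax != 1L) arr <- aperm(arr, order(c(ax, setdiff(1:3, ax))))
  if (is.null(template)) {
    as_volume(arr)
  } else {
    t <- as_volume(template)
    as_volume(arr, spacing = t$spacing, axial_axis = t$axial_axis,
              dtype_note = t$dtype_note)
  }
}

#' Binarize a mask volume
#'
#' @param mask_volume numeric volume or array (e.g. a `{0, 255}` TIFF mask).
#' @param positive_rule function mapping the numeric array to logical;
#'   default marks values strictly greater than zero as foreground.
#' @return an `is_volume` whose data is 0/1.
#' @export
binarize_mask <- function(mask_volume, positive_rule = function(x) x > 0) {
  v <- as_volume(mask_volume)
  if (!is.numeric(v$data)) stop("mask must be numeric", call. = FALSE)
  bin <- array(as.numeric(positive_rule(v$data)), dim(v$data))
  if (!any(bin > 0)) warning("binarized mask is empty", call. = FALSE)
  as_volume(bin, spacing = v$spacing, axial_axis = v$axial_axis,
            dtype_note = "binary")
}
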