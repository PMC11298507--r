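# Pluggable 2D segmenter contract and reference backends.
#
# A backend maps one normalized [0, 255] image tile to a same-shape
# probability map in [0, 1]. Any 2D model satisfying this contract can be
# plugged into the pipeline; the deterministic threshold-opening backend
# below is scale-sensitive by construction, which reproduces at desk scale
# the ir-dependence that motivates the multi-scale ensemble: structures
# narrower than its structuring element vanish at ir = 1 and reappear once
# up-sampling magnifies them past the element's diameter.

#' Construct a segmenter backend
#'
#' @param name backend name (provenance).
#' @param predict function mapping a tile matrix to a same-shape probability
#'   matrix in `[0, 1]`.
#' @param deterministic logical flag recorded in provenance.
#' @return a `segmenter_backend`.
#' @export
make_backend <- function(name, predict, deterministic = TRUE) {
  stopifnot(is.character(name), is.function(predict))
  structure(list(name = name, predict = predict, deterministic = deterministic),
            class = "segmenter_backend")
}

#' Apply a backend to one tile, validating the contract
#'
#' @param backend a `segmenter_backend`.
#' @param tile 2D matrix.
#' @return probability matrix, same shape as `tile`, values in `[0, 1]`.
#' @export
predict_tile <- function(backend, tile) {
  out <- backend$predict(tile)
  if (!is.matrix(out) || !identical(dim(out), dim(tile))) {
    stop(sprintf("backend '%s' returned wrong shape", backend$name), call. = FALSE)
  }
  if (min(out) < 0 || max(out) > 1) {
    stop(sprintf("backend '%s' returned values outside [0, 1]", backend$name),
         call. = FALSE)
  }
  out
}

# disk-shaped structuring element offsets (dy, dx) with dy^2 + dx^2 <= r^2
#' @keywords internal
disk_offsets <- function(radius) {
  r <- as.integer(floor(radius))
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g[g$dy^2 + g$dx^2 <= radius^2, , drop = FALSE]
}

# shift a binary matrix by (dy, dx), padding with `fill`
#' @keywords internal
shift_mat <- function(m, dy, dx, fill) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  rs <- max(1, 1 - dy):min(h, h - dy)
  cs <- max(1, 1 - dx):min(w, w - dx)
  out[rs, cs] <- m[rs + dy, cs + dx, drop = FALSE]
  out
}

#' Binary erosion with a disk structuring element
#'
#' Pixels outside the image are treated as background, so structures touching
#' the border erode like interior ones.
#'
#' @param mask binary matrix.
#' @param radius disk radius in pixels (0 = identity).
#' @return binary matrix.
#' @export
binary_erode <- function(mask, radius) {
  if (radius <= 0) return(mask)
  offs <- disk_offsets(radius)
  out <- matrix(1, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(offs))) {
    out <- out * shift_mat(mask, offs$dy[i], offs$dx[i], fill = 0)
  }
  out
}

#' Binary dilation with a disk structuring element
#' @inheritParams binary_erode
#' @return binary matrix.
#' @export
binary_dilate <- function(mask, radius) {
  if (radius <= 0) return(mask)
  offs <- disk_offsets(radius)
  out <- matrix(0, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(offs))) {
    out <- pmax(out, shift_mat(mask, offs$dy[i], offs$dx[i], fill = 0))
  }
  out
}

#' Binary opening (erosion then dilation) with a disk element
#' @inheritParams binary_erode
#' @return binary matrix; structures narrower than the element vanish.
#' @export
binary_opening <- function(mask, radius) {
  binary_dilate(binary_erode(mask, radius), radius)
}

#' Deterministic threshold-plus-opening segmenter backend
#'
#' Probability map = morphological opening (disk of `opening_radius`) of the
#' binary map `image < tau`, cast to {0, 1}. On windowed lung CT the airway
#' lumen is the dark band, so thresholding below `tau` marks lumen
#' candidates; the opening removes structures narrower than the element
#' (diameter `2 * opening_radius + 1`), making the backend scale-sensitive.
#' The default `tau = 55` is the midpoint of the default phantom's windowed
#' lumen (42.5) and parenchyma (68.0) bands.
#'
#' @param tau intensity threshold on `[0, 255]`.
#' @param opening_radius disk radius in pixels (>= 0).
#' @return a `segmenter_backend`.
#' @export
threshold_opening_backend <- function(tau = 55, opening_radius = 1) {
  check_scalar_number(tau, "tau", lower = 0, upper = 255)
  check_scalar_number(opening_radius, "opening_radius", lower = 0)
  make_backend(
    name = sprintf("threshold-opening(tau=%g, r=%g)", tau, opening_radius),
    predict = function(tile) {
      binary_opening((tile < tau) * 1, opening_radius)
    },
    deterministic = TRUE
  )
}

#' Identity-probability backend: tile / 255
#'
#' Plumbing/testing backend mapping normalized intensity linearly to
#' probability.
#' @return a `segmenter_backend`.
#' @export
identity_backend <- function() {
  make_backend("identity", function(tile) clamp(tile / 255, 0, 1))
}

#' Constant-probability backend
#' @param p constant probability in `[0, 1]`.
#' @return a `segmenter_backend`.
#' @export
constant_backend <- function(p = 0) {
  check_scalar_number(p, "p", lower = 0, upper = 1)
  make_backend(sprintf("constant(%g)", p),
               function(tile) matrix(p, nrow(tile), ncol(tile)))
}
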