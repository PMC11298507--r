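# internal helpers shared across modules

#' @keywords internal
abort_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

#' @keywords internal
check_scalar_number <- function(x, field, lower = -Inf, upper = Inf,
                                integer = FALSE, strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_field(field, "must be a single finite number")
  }
  if (integer && x != as.integer(x)) abort_field(field, "must be an integer")
  if (strict_lower) {
    if (x <= lower) abort_field(field, sprintf("must be > %s", lower))
  } else if (x < lower) {
    abort_field(field, sprintf("must be >= %s", lower))
  }
  if (x > upper) abort_field(field, sprintf("must be <= %s", upper))
  invisible(x)
}

#' @keywords internal
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Run code with a temporary RNG state so generators are deterministic given a
# seed without clobbering the caller's stream.
#' @keywords internal
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Nearest source index (0-based) under the shared half-pixel-centre convention;
# ties resolved toward the smaller index.
#' @keywords internal
nn_index0 <- function(x, n) {
  x <- clamp(x, 0, n - 1)
  as.integer(clamp(ceiling(x - 0.5), 0, n - 1))
}

# Separable Gaussian kernel; radius 3*sigma, always odd length.
#' @keywords internal
gaussian_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# 1D convolution along matrix rows with edge replication (constraint: output
# dims equal input dims, mass preserved on constant inputs).
#' @keywords internal
conv_rows <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  if (r == 0L) return(m)
  n <- nrow(m)
  idx <- clamp(seq_len(n + 2L * r) - r, 1L, n)
  padded <- m[idx, , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(k)) {
    out <- out + k[j] * padded[seq_len(n) + (j - 1L), , drop = FALSE]
  }
  out
}

#' Gaussian blur of a 2D image (separable, edge-replicated)
#'
#' @param image numeric matrix.
#' @param sigma standard deviation in pixels; `sigma = 0` is the identity.
#' @return blurred matrix of the same dimensions.
#' @export
gaussian_blur_2d <- function(image, sigma) {
  if (!is.matrix(image)) stop("`image` must be a matrix", call. = FALSE)
  if (sigma <= 0) return(image)
  k <- gaussian_kernel(sigma)
  t(conv_rows(t(conv_rows(image, k)), k))
}

#' @keywords internal
gaussian_blur_3d <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  k <- gaussian_kernel(sigma)
  d <- dim(arr)
  # blur along each axis in turn by reshaping to a matrix with that axis first
  for (ax in 1:3) {
    perm <- c(ax, setdiff(1:3, ax))
    a <- aperm(arr, perm)
    dm <- dim(a)
    m <- conv_rows(matrix(a, nrow = dm[1]), k)
    arr <- aperm(array(m, dm), order(perm))
  }
  arr
}
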