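#' Window/level intensity mapping parameters
#'
#' The lung window used throughout the pipeline defaults to width
#' W = 1500 HU and level L = -500 HU, emphasising lung tissue. Window bounds
#' are the radiological convention `[L - W/2, L + W/2]`.
#'
#' @param W window width in HU (> 0).
#' @param L window level (centre) in HU.
#' @return an object of class `window_level`.
#' @export
window_level <- function(W = 1500, L = -500) {
  check_scalar_number(W, "W", lower = 0, strict_lower = TRUE)
  check_scalar_number(L, "L")
  structure(list(W = as.numeric(W), L = as.numeric(L)), class = "window_level")
}

#' Normalise HU intensities to the 0-255 display range
#'
#' Linear window/level mapping: `g = clamp((I - (L - W/2)) / W, 0, 1) * 255`.
#' The result is kept in floating point; quantisation to 8 bits happens only
#' at TIFF export, to avoid double-rounding drift through the interpolation
#' pipeline. The map is monotone non-decreasing in the input intensity.
#'
#' @param volume volume or 3D array in Hounsfield units.
#' @param wl a [window_level()] object.
#' @return an `is_volume` with values in `[0, 255]`.
#' @examples
#' v <- as_volume(array(c(-1250, -500, 250), c(1, 1, 3)))
#' window_level_normalize(v, window_level(1500, -500))$data
#' @export
window_level_normalize <- function(volume, wl = window_level()) {
  if (!inherits(wl, "window_level")) wl <- do.call(window_level, as.list(wl))
  v <- as_volume(volume)
  lo <- wl$L - wl$W / 2
  g <- clamp((v$data - lo) / wl$W, 0, 1) * 255
  as_volume(g, spacing = v$spacing, axial_axis = v$axial_axis,
            dtype_note = "normalized-0-255")
}

#' Unsharp masking (optional pre-processing)
#'
#' `image + amount * (image - gaussian_blur(image, radius))`, clamped to the
#' valid intensity range. With `amount = 0` this is the identity; on a
#' constant image it is the identity for any amount. Used to counteract the
#' interpolation blur that grows with the interpolation ratio.
#'
#' @param image 2D numeric matrix.
#' @param amount sharpening strength (>= 0).
#' @param radius Gaussian sigma in pixels (> 0).
#' @param range valid intensity range to clamp to (default `c(0, 255)`).
#' @return sharpened matrix.
#' @export
unsharp_mask <- function(image, amount, radius, range = c(0, 255)) {
  if (!is.matrix(image)) stop("`image` must be a matrix", call. = FALSE)
  check_scalar_number(amount, "amount", lower = 0)
  check_scalar_number(radius, "radius", lower = 0, strict_lower = TRUE)
  if (amount == 0) return(image)
  out <- image + amount * (image - gaussian_blur_2d(image, radius))
  clamp(out, range[1], range[2])
}

#' Read a volume from disk
#'
#' Dispatcher over the supported on-disk formats. DICOM series are not
#' supported in this build (no DICOM codec is available in the target
#' library); requesting them raises an informative error.
#'
#' @param path file (NIfTI) or directory / file vector (TIFF stack).
#' @param format `"nifti"`, `"tiff"` or `"dicom"`; the default guesses from
#'   the path (`.nii`/`.nii.gz` -> NIfTI, directory or `.tif` -> TIFF stack).
#' @param ... passed to the format reader.
#' @return an `is_volume` with ascending slice order along the axial axis.
#' @export
read_volume <- function(path, format = c("auto", "nifti", "tiff", "dicom"), ...) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (length(path) > 1L || dir.exists(path[1]) ||
                  grepl("\\.tiff?$", path[1])) {
      "tiff"
    } else if (grepl("\\.nii(\\.gz)?$", path[1])) {
      "nifti"
    } else {
      stop("cannot guess format of ", path[1],
           "; pass format = 'nifti' or 'tiff'", call. = FALSE)
    }
  }
  switch(format,
         nifti = read_nifti(path, ...),
         tiff = read_tiff_stack(path, ...),
         dicom = stop("DICOM reading is not supported in this build; ",
                      "convert the series to NIfTI or a TIFF stack first",
                      call. = FALSE))
}
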