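# Synthetic HRCT-like airway-tree phantom with exact ground truth.
#
# The phantom emulates what matters to a scale-sensitive 2D segmenter on lung
# CT: dark tubular lumina whose calibre halves per generation, brighter wall
# rings, noisy parenchyma background and point-spread blur. Ground truth is
# the (pre-noise, pre-blur) lumen, matching airway-lumen segmentation
# convention.

#' Specification of a synthetic airway-tree phantom
#'
#' Defaults describe a desk-scale phantom: a 96^3 grid, four generations of a
#' binary tree whose radius halves per generation (8, 4, 2, 1 voxels), and
#' intensity bands (`hu_lumen` = -1000, `hu_parenchyma` = -850, `hu_wall` =
#' -100 HU) chosen so the standard lung window (W = 1500, L = -500) maps them
#' to distinct 8-bit bands (42.5, 68.0, 195.5). Terminal branches are 2
#' voxels in diameter: invisible to a diameter-3 structuring element at
#' interpolation ratio 1 but resolvable once up-sampled.
#'
#' @param grid_shape voxels per axis, axial first (z, y, x).
#' @param G number of generations (root = generation 0).
#' @param root_radius trachea radius in voxels.
#' @param radius_decay per-generation radius factor, in (0, 1).
#' @param length_root root segment length in voxels.
#' @param length_decay per-generation length factor, in (0, 1].
#' @param branch_half_angle bifurcation half-angle in degrees.
#' @param angle_jitter uniform jitter added to the half-angle, degrees.
#' @param wall_thickness airway wall shell thickness in voxels.
#' @param hu_lumen,hu_wall,hu_parenchyma intensity bands in HU; must satisfy
#'   `hu_lumen < hu_parenchyma < hu_wall`.
#' @param noise_sigma additive Gaussian noise SD in HU.
#' @param psf_sigma Gaussian point-spread blur sigma in voxels.
#' @param min_radius recursion stops when a child radius would fall below this.
#' @param seed integer RNG seed; identical specs give bit-identical phantoms.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(96, 96, 96), G = 4, root_radius = 8,
                         radius_decay = 0.5, length_root = 28,
                         length_decay = 0.8, branch_half_angle = 35,
                         angle_jitter = 5, wall_thickness = 2,
                         hu_lumen = -1000, hu_wall = -100,
                         hu_parenchyma = -850, noise_sigma = 20,
                         psf_sigma = 0.7, min_radius = 0.75, seed = 42L) {
  if (!is.numeric(grid_shape) || length(grid_shape) != 3L ||
      any(grid_shape < 8) || any(grid_shape != round(grid_shape))) {
    abort_field("grid_shape", "must be 3 integers >= 8")
  }
  check_scalar_number(G, "G", lower = 1, integer = TRUE)
  check_scalar_number(radius_decay, "radius_decay", lower = 0, upper = 1,
                      strict_lower = TRUE)
  if (radius_decay >= 1) abort_field("radius_decay", "must be < 1")
  check_scalar_number(length_decay, "length_decay", lower = 0, upper = 1,
                      strict_lower = TRUE)
  check_scalar_number(min_radius, "min_radius", lower = 0, strict_lower = TRUE)
  check_scalar_number(root_radius, "root_radius", lower = min_radius)
  check_scalar_number(length_root, "length_root", lower = 1)
  check_scalar_number(branch_half_angle, "branch_half_angle", lower = 0, upper = 89)
  check_scalar_number(angle_jitter, "angle_jitter", lower = 0)
  check_scalar_number(wall_thickness, "wall_thickness", lower = 0)
  check_scalar_number(noise_sigma, "noise_sigma", lower = 0)
  check_scalar_number(psf_sigma, "psf_sigma", lower = 0)
  check_scalar_number(seed, "seed", integer = TRUE)
  if (!(hu_lumen < hu_parenchyma && hu_parenchyma < hu_wall)) {
    abort_field("hu_lumen/hu_parenchyma/hu_wall",
                "must satisfy hu_lumen < hu_parenchyma < hu_wall")
  }
  structure(
    list(grid_shape = as.integer(grid_shape), G = as.integer(G),
         root_radius = root_radius, radius_decay = radius_decay,
         length_root = length_root, length_decay = length_decay,
         branch_half_angle = branch_half_angle, angle_jitter = angle_jitter,
         wall_thickness = wall_thickness, hu_lumen = hu_lumen,
         hu_wall = hu_wall, hu_parenchyma = hu_parenchyma,
         noise_sigma = noise_sigma, psf_sigma = psf_sigma,
         min_radius = min_radius, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# Rodrigues rotation of vector v about unit axis k by angle theta (radians).
#' @keywords internal
rotate_vec <- function(v, k, theta) {
  v * cos(theta) +
    c(k[2] * v[3] - k[3] * v[2],
      k[3] * v[1] - k[1] * v[3],
      k[1] * v[2] - k[2] * v[1]) * sin(theta) +
    k * sum(k * v) * (1 - cos(theta))
}

#' Generate the branch list of a phantom airway tree
#'
#' Recursive binary bifurcation from a root segment along the axial (z) axis.
#' Bifurcation planes alternate between the two lateral axes per generation,
#' with seeded angle jitter, which fills 3D space without a collision solver.
#' Recursion stops at generation `G - 1` or when the child radius would fall
#' below `min_radius`; branches that would leave the grid are dropped with a
#' warning. Deterministic given `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @return list of branches, each a list with fields `generation` (0-based),
#'   `start`, `end` (voxel coordinates, axial first), `radius` and `parent`
#'   (index into the list, `NA` for the root).
#' @export
generate_tree <- function(spec) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  d <- spec$grid_shape
  with_local_seed(spec$seed, {
    branches <- list()
    inside <- function(p, radius) {
      margin <- radius + spec$wall_thickness
      all(p >= 1 + margin) && all(p <= d - margin)
    }
    grow <- function(start, dir, length, radius, generation, parent) {
      end <- start + dir * length
      if (!inside(start, radius) || !inside(end, radius)) {
        warning(sprintf("dropping generation-%d branch leaving the grid",
                        generation), call. = FALSE)
        return(invisible(NULL))
      }
      branches[[length(branches) + 1L]] <<- list(
        generation = generation, start = start, end = end,
        radius = radius, parent = parent)
      this_idx <- length(branches)
      child_radius <- radius * spec$radius_decay
      if (generation + 1L > spec$G - 1L || child_radius < spec$min_radius) {
        return(invisible(NULL))
      }
      # alternate the bifurcation plane: rotate about x-axis on odd child
      # generations, about y-axis on even ones (coordinates are (z, y, x))
      axis <- if ((generation + 1L) %% 2L == 1L) c(0, 0, 1) else c(0, 1, 0)
      for (sgn in c(-1, 1)) {
        theta <- sgn * (spec$branch_half_angle +
                          stats::runif(1, -spec$angle_jitter, spec$angle_jitter))
        cdir <- rotate_vec(dir, axis, theta * pi / 180)
        cdir <- cdir / sqrt(sum(cdir^2))
        grow(end, cdir, length * spec$length_decay, child_radius,
             generation + 1L, this_idx)
      }
      invisible(NULL)
    }
    root_start <- c(2 + spec$root_radius + spec$wall_thickness,
                    ceiling(d[2] / 2), ceiling(d[3] / 2))
    grow(root_start, c(1, 0, 0), spec$length_root, spec$root_radius, 0L, NA_integer_)
    branches
  })
}

# Distance from every voxel centre of a sub-grid to a line segment; fills the
# supplied logical accumulators for lumen and wall membership.
#' @keywords internal
mark_branch <- function(lumen, wall, branch, wall_thickness, d) {
  a <- branch$start; b <- branch$end; r <- branch$radius
  reach <- r + wall_thickness + 1
  lo <- pmax(floor(pmin(a, b) - reach), 1)
  hi <- pmin(ceiling(pmax(a, b) + reach), d)
  zs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; xs <- lo[3]:hi[3]
  nz <- length(zs); ny <- length(ys); nx <- length(xs)
  # voxel-centre coordinates of the bbox sub-grid, one array per axis
  Z <- array(rep(zs, times = ny * nx), c(nz, ny, nx))
  Y <- array(rep(rep(ys, each = nz), times = nx), c(nz, ny, nx))
  X <- array(rep(xs, each = nz * ny), c(nz, ny, nx))
  ab <- b - a
  len2 <- sum(ab^2)
  t <- ((Z - a[1]) * ab[1] + (Y - a[2]) * ab[2] + (X - a[3]) * ab[3]) / len2
  t <- clamp(t, 0, 1)
  dist2 <- (Z - (a[1] + t * ab[1]))^2 + (Y - (a[2] + t * ab[2]))^2 +
    (X - (a[3] + t * ab[3]))^2
  lum_box <- dist2 <= r^2
  wal_box <- dist2 <= (r + wall_thickness)^2
  lumen[zs, ys, xs] <- lumen[zs, ys, xs] | lum_box
  wall[zs, ys, xs] <- wall[zs, ys, xs] | wal_box
  list(lumen = lumen, wall = wall)
}

#' Rasterize a branch list into a phantom CT volume
#'
#' Lumen voxels (distance to the nearest branch axis at most the branch
#' radius) get `hu_lumen`; the wall shell gets `hu_wall`; everything else is
#' `hu_parenchyma`. Seeded Gaussian noise and a Gaussian point-spread blur are
#' then applied to the image. The ground-truth `lumen_mask` is the pre-noise,
#' pre-blur lumen set, so it is invariant to `noise_sigma` and `psf_sigma`.
#'
#' @param branches output of [generate_tree()] on the same spec.
#' @param spec the [phantom_spec()].
#' @return a `phantom_volume`: list with `image` (HU volume), `lumen_mask`
#'   (binary volume) and `branches`.
#' @export
rasterize <- function(branches, spec) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  if (!length(branches)) stop("empty branch list", call. = FALSE)
  d <- spec$grid_shape
  lumen <- array(FALSE, d)
  wall <- array(FALSE, d)
  for (br in branches) {
    marked <- mark_branch(lumen, wall, br, spec$wall_thickness, d)
    lumen <- marked$lumen
    wall <- marked$wall
  }
  img <- array(spec$hu_parenchyma, d)
  img[wall] <- spec$hu_wall
  img[lumen] <- spec$hu_lumen
  if (spec$noise_sigma > 0) {
    img <- img + with_local_seed(spec$seed + 1013L,
                                 array(stats::rnorm(prod(d), 0, spec$noise_sigma), d))
  }
  if (spec$psf_sigma > 0) img <- gaussian_blur_3d(img, spec$psf_sigma)
  structure(
    list(image = as_volume(img, dtype_note = "HU"),
         lumen_mask = as_volume(array(as.numeric(lumen), d), dtype_note = "binary"),
         branches = branches,
         spec = spec),
    class = "phantom_volume"
  )
}

#' Generate a complete phantom in one call
#'
#' @param spec a [phantom_spec()].
#' @return a `phantom_volume` (see [rasterize()]).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  rasterize(generate_tree(spec), spec)
}

#' @export
print.phantom_volume <- function(x, ...) {
  cat(sprintf("<phantom_volume> %s voxels, %d branches (generations 0-%d), %d lumen voxels\n",
              paste(dim(x$image$data), collapse = " x "), length(x$branches),
              max(vapply(x$branches, `[[`, integer(1), "generation")),
              sum(x$lumen_mask$data)))
  invisible(x)
}

#' Affine gradient test image
#'
#' An n-by-n image whose intensity is an affine function of position:
#' `value = slope_row * (row - 1) + slope_col * (col - 1) + offset` (0-based
#' position). Affine images are the exactness class of bilinear
#' interpolation, which is what makes this the right probe for seam and
#' artefact analyses: any whole-image bilinear up-sample reproduces the ramp
#' exactly in the interior.
#'
#' @param n image side (>= 2).
#' @param orientation `"row"`, `"col"` or `"diag"` preset; sets the slopes
#'   unless given explicitly.
#' @param slope ramp slope per pixel for the preset direction.
#' @param offset additive constant.
#' @param slope_row,slope_col explicit slopes, overriding `orientation`.
#' @return n x n numeric matrix.
#' @examples
#' gradient_image(2, "row")  # rows 0 and 1
#' @export
gradient_image <- function(n, orientation = c("row", "col", "diag"),
                           slope = 1, offset = 0,
                           slope_row = NULL, slope_col = NULL) {
  check_scalar_number(n, "n", lower = 2, integer = TRUE)
  orientation <- match.arg(orientation)
  if (is.null(slope_row) || is.null(slope_col)) {
    slope_row <- switch(orientation, row = slope, col = 0, diag = slope)
    slope_col <- switch(orientation, row = 0, col = slope, diag = slope)
  }
  r <- matrix(rep(0:(n - 1), times = n), n, n)
  cl <- matrix(rep(0:(n - 1), each = n), n, n)
  slope_row * r + slope_col * cl + offset
}

#' Write a phantom fixture to disk
#'
#' NIfTI: `image.nii.gz` (float32 HU) and `mask.nii.gz` (uint8), read back
#' bit-exactly for the integer-encoded mask. TIFF: per-slice 16-bit stacks
#' under `image/` and `mask/`, with the image stored as `round(HU) + 1024`
#' (documented in the sidecar). A JSON sidecar `phantom.json` records the
#' spec and the branch table.
#'
#' @param volume a `phantom_volume`.
#' @param path output directory (created).
#' @param format `"nifti"` or `"tiff"`.
#' @return named list of written paths, invisibly.
#' @export
write_phantom_fixture <- function(volume, path, format = c("nifti", "tiff")) {
  if (!inherits(volume, "phantom_volume")) {
    stop("`volume` must be a phantom_volume", call. = FALSE)
  }
  if (!is.character(format) || !all(format %in% c("nifti", "tiff"))) {
    stop("unsupported format; supported formats: nifti, tiff", call. = FALSE)
  }
  format <- match.arg(format)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  branches_df <- data.frame(
    generation = vapply(volume$branches, `[[`, integer(1), "generation"),
    radius = vapply(volume$branches, `[[`, numeric(1), "radius"),
    parent = vapply(volume$branches, `[[`, integer(1), "parent"),
    t(vapply(volume$branches, function(b) c(b$start, b$end), numeric(6)))
  )
  names(branches_df)[4:9] <- c("z0", "y0", "x0", "z1", "y1", "x1")
  sidecar <- file.path(path, "phantom.json")
  jsonlite::write_json(
    list(spec = unclass(volume$spec), branches = branches_df,
         tiff_image_offset = if (format == "tiff") 1024 else NULL),
    sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (format == "nifti") {
    img <- file.path(path, "image.nii.gz")
    msk <- file.path(path, "mask.nii.gz")
    write_nifti(volume$image, img, datatype = "float32")
    write_nifti(volume$lumen_mask, msk, datatype = "uint8")
    invisible(list(image = img, mask = msk, sidecar = sidecar))
  } else {
    img_dir <- file.path(path, "image")
    msk_dir <- file.path(path, "mask")
    shifted <- as_volume(clamp(round(volume$image$data) + 1024, 0, 65535))
    imgs <- write_tiff_stack(shifted, img_dir, prefix = "image", bits = 16L)
    msks <- write_tiff_stack(volume$lumen_mask, msk_dir, prefix = "mask", bits = 8L)
    invisible(list(image = imgs, mask = msks, sidecar = sidecar))
  }
}
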