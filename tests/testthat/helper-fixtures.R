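# Shared fixtures. Expensive objects (the default phantom and the full
# four-ratio pipeline run) are computed once per test session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# the seeded default phantom: the stated desk-scale world (96^3, G = 4,
# radii 8, 4, 2, 1 voxels)
default_phantom <- function() {
  cached("default_phantom", generate_phantom(phantom_spec()))
}

default_phantom_norm <- function() {
  cached("default_phantom_norm", window_level_normalize(default_phantom()$image))
}

# full 4-ratio pipeline run on the default phantom with the default backend
default_pipeline <- function() {
  cached("default_pipeline", {
    run_interpolation_split(
      default_phantom_norm(), threshold_opening_backend(),
      ensemble_config(irs = c(1, 2, 4, 8), tile_size = 64),
      gt_mask = default_phantom()$lumen_mask)
  })
}

# Constructed scale-property fixture: a thick axial trunk plus four thin
# axis-aligned terminal branches whose in-plane lumen is 3 voxels wide --
# below the diameter-5 structuring element of the radius-2 opening backend at
# ir = 1, above it at ir = 4. No PSF so the lumen/parenchyma contrast of the
# thin branches survives rasterization.
scale_property_phantom <- function() {
  cached("scale_property_phantom", {
    spec <- phantom_spec(grid_shape = c(64, 64, 64), noise_sigma = 10,
                         psf_sigma = 0, seed = 3)
    trunk <- list(generation = 0L, start = c(8, 32, 32), end = c(52, 32, 32),
                  radius = 5, parent = NA_integer_)
    mk_term <- function(y, x) {
      list(generation = 1L, start = c(16, y, x), end = c(48, y, x),
           radius = 1.5, parent = 1L)
    }
    branches <- c(list(trunk),
                  lapply(list(c(20, 20), c(20, 44), c(44, 20), c(44, 44)),
                         function(p) mk_term(p[1], p[2])))
    ph <- rasterize(branches, spec)
    terminal_mask <- rasterize(
      branches[-1],
      phantom_spec(grid_shape = c(64, 64, 64), noise_sigma = 0, psf_sigma = 0)
    )$lumen_mask$data
    list(phantom = ph,
         norm = window_level_normalize(ph$image),
         terminal_mask = terminal_mask,
         backend = threshold_opening_backend(tau = 55, opening_radius = 2))
  })
}

random_binary_matrix <- function(n, m = n, p = 0.3) {
  matrix(as.numeric(stats::rbinom(n * m, 1, p)), n, m)
}
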