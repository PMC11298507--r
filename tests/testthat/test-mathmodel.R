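# mathmodel: bilinear cell, crop-then-upscale comparator, seams, sharpness

test_that("bilinear_point reproduces corners, the worked centre, and affine maps", {
  cell <- bilinear_cell(0, 1, 2, 3)
  expect_identical(bilinear_point(cell, 0, 0), 0)   # f11 at (x1, y1)
  expect_identical(bilinear_point(cell, 1, 0), 1)   # f21
  expect_identical(bilinear_point(cell, 0, 1), 2)   # f12
  expect_equal(bilinear_point(cell, 0.5, 0.5), 1.5) # worked example

  # any affine f(x, y) = a x + b y + c is reproduced exactly on a query grid
  set.seed(30)
  for (i in 1:10) {
    a <- stats::rnorm(1); b <- stats::rnorm(1); cc <- stats::rnorm(1)
    x1 <- stats::runif(1, -5, 0); x2 <- x1 + stats::runif(1, 0.5, 4)
    y1 <- stats::runif(1, -5, 0); y2 <- y1 + stats::runif(1, 0.5, 4)
    f <- function(x, y) a * x + b * y + cc
    cell <- bilinear_cell(f(x1, y1), f(x2, y1), f(x1, y2), f(x2, y2),
                          x1, x2, y1, y2)
    qx <- seq(x1, x2, length.out = 7)
    qy <- seq(y1, y2, length.out = 7)
    for (x in qx) for (y in qy) {
      expect_lt(abs(bilinear_point(cell, x, y) - f(x, y)), 1e-9)
    }
  }
  expect_error(bilinear_cell(0, 1, 2, 3, x1 = 1, x2 = 1), "degenerate")
  expect_error(bilinear_point(cell, 10, 0), "outside")
})

test_that("bilinear_point matches upsample_image at every output pixel", {
  set.seed(31)
  img <- matrix(stats::runif(36, 0, 100), 6, 6)
  ir <- 3
  up <- upsample_image(img, ir)
  for (o_r in seq_len(6 * ir)) {
    for (o_c in seq_len(6 * ir)) {
      sr <- min(max((o_r - 0.5) / ir - 0.5, 0), 5)
      sc <- min(max((o_c - 0.5) / ir - 0.5, 0), 5)
      r0 <- min(floor(sr), 4); c0 <- min(floor(sc), 4)
      cell <- bilinear_cell(img[r0 + 1, c0 + 1], img[r0 + 1, c0 + 2],
                            img[r0 + 2, c0 + 1], img[r0 + 2, c0 + 2],
                            x1 = c0, x2 = c0 + 1, y1 = r0, y2 = r0 + 1)
      expect_lt(abs(bilinear_point(cell, sc, sr) - up[o_r, o_c]), 1e-9)
    }
  }
})

test_that("crop_then_upscale has the documented geometry and constant behaviour", {
  ramp <- gradient_image(4, "diag")
  out <- crop_then_upscale(ramp, 2, 2)
  expect_identical(dim(out), c(8L, 8L))          # 4x4 blocks merge to 8x8
  expect_identical(crop_then_upscale(ramp, 2, 1), ramp)
  const <- matrix(3, 8, 8)
  expect_equal(crop_then_upscale(const, 2, 2), upsample_image(const, 2))
  expect_error(crop_then_upscale(matrix(0, 5, 5), 2, 2), "divisible")
})

test_that("intensity_profile selects rows/columns unchanged", {
  ramp <- gradient_image(6, "col", slope = 2)
  expect_identical(intensity_profile(ramp, "row", 3), ramp[3, ])
  expect_identical(intensity_profile(ramp, "column", 5), ramp[, 5])
  expect_true(all(diff(intensity_profile(ramp, "row", 1)) > 0))  # monotone on a column ramp
  expect_length(intensity_profile(ramp, "column", 2), 6L)
  expect_error(intensity_profile(ramp, "row", 9), "index")
})

test_that("seam statistic: zero on constants and whole-image ramps, positive for crops", {
  const_rep <- seam_discontinuity(matrix(1, 8, 8), list(cols = 5))
  expect_identical(const_rep$seam_step, 0)
  expect_identical(const_rep$interior_step, 0)
  expect_identical(const_rep$discontinuity, 0)
  expect_error(seam_discontinuity(matrix(1, 8, 8), list(cols = integer(0))), "seam")

  for (ir in c(2, 4)) {
    n <- 8; block <- 4
    ramp <- gradient_image(n, "diag", slope = 3, offset = 10)
    seams <- list(cols = block * ir * seq_len(n / block - 1) + 1,
                  rows = block * ir * seq_len(n / block - 1) + 1)
    whole <- seam_discontinuity(upsample_image(ramp, ir), seams, margin = ir %/% 2)
    split <- seam_discontinuity(crop_then_upscale(ramp, block, ir), seams,
                                margin = ir %/% 2)
    expect_lt(abs(whole$discontinuity), 1e-9)   # uniform steps, no seams
    expect_gt(split$discontinuity, 0)           # clamped block edges jump
  }
})

test_that("diagonal Laplacian sharpness: kernel arithmetic, invariances, blur", {
  expect_identical(diagonal_laplacian_sharpness(matrix(7, 5, 5)), 0)
  centre <- matrix(0, 3, 3); centre[2, 2] <- 1
  expect_identical(diagonal_laplacian_sharpness(centre), 4)  # |2-0-0| + |2-0-0|
  expect_error(diagonal_laplacian_sharpness(matrix(0, 2, 3)), "3 x 3")

  set.seed(32)
  img <- matrix(stats::runif(400, 0, 255), 20, 20)
  s <- diagonal_laplacian_sharpness(img)
  expect_equal(diagonal_laplacian_sharpness(img + 40), s)        # translation
  expect_equal(diagonal_laplacian_sharpness(img * 2.5), 2.5 * s) # contrast scaling
  for (i in 1:5) {
    r <- matrix(stats::runif(256, 0, 255), 16, 16)
    expect_lt(diagonal_laplacian_sharpness(gaussian_blur_2d(r, 1)),
              diagonal_laplacian_sharpness(r))
  }
  # affine images have zero diagonal second differences
  expect_lt(diagonal_laplacian_sharpness(gradient_image(9, "diag", slope = 5)), 1e-12)
})

test_that("paired_sharpness_study matches stats::t.test and handles degeneracies", {
  set.seed(33)
  existing <- lapply(1:8, function(i) matrix(stats::runif(64, 0, 255), 8, 8))
  interp <- lapply(existing, function(m) unsharp_mask(m, 0.5, 1))
  study <- paired_sharpness_study(existing, interp)
  ref <- stats::t.test(study$sharpness_interp_split, study$sharpness_existing,
                       paired = TRUE)
  expect_equal(study$t, unname(ref$statistic))
  expect_equal(study$p_value, ref$p.value)
  expect_identical(study$df, 7L)

  same <- paired_sharpness_study(existing, existing)
  expect_true(same$degenerate)
  expect_true(is.na(same$t))

  # constant nonzero differences: SD = 0 with nonzero mean -> infinite evidence
  base <- matrix(0, 3, 3); base[2, 2] <- 1
  a <- lapply(c(1, 1, 1, 1), function(k) base)
  b <- lapply(c(1, 1, 1, 1), function(k) base * 1.25)  # sharpness 4 -> 5, d = 1 each
  inf_study <- paired_sharpness_study(a, b)
  expect_identical(inf_study$t, Inf)
  expect_identical(inf_study$p_value, 0)
  expect_error(paired_sharpness_study(existing[1], interp[1]), "pairs")
})
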