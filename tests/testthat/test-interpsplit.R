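# interpsplit core: resampling, tiling, counting, round trips

test_that("upsample_image doubles dimensions at ir = 2 and is identity at ir = 1", {
  img <- matrix(stats::runif(512 * 512), 512, 512)
  up <- upsample_image(img, 2)
  expect_identical(dim(up), c(1024L, 1024L))
  expect_identical(upsample_image(img, 1), img)
  expect_error(upsample_image(img, 0), "ir")
  expect_error(upsample_image(img, 1.5), "ir")
})

test_that("upsample_image agrees with the closed-form bilinear oracle", {
  # brute force via bilinear_point under the half-pixel-centre convention
  oracle_upsample <- function(img, ir) {
    h <- nrow(img); w <- ncol(img)
    out <- matrix(NA_real_, h * ir, w * ir)
    for (o_r in seq_len(h * ir)) {
      for (o_c in seq_len(w * ir)) {
        sr <- min(max((o_r - 1 + 0.5) / ir - 0.5, 0), h - 1)
        sc <- min(max((o_c - 1 + 0.5) / ir - 0.5, 0), w - 1)
        r0 <- min(floor(sr), h - 2); c0 <- min(floor(sc), w - 2)
        cell <- bilinear_cell(img[r0 + 1, c0 + 1], img[r0 + 1, c0 + 2],
                              img[r0 + 2, c0 + 1], img[r0 + 2, c0 + 2],
                              x1 = c0, x2 = c0 + 1, y1 = r0, y2 = r0 + 1)
        out[o_r, o_c] <- bilinear_point(cell, sc, sr)
      }
    }
    out
  }
  set.seed(20)
  for (ir in c(2, 3, 4)) {
    img <- matrix(stats::runif(64, 0, 255), 8, 8)
    expect_lt(max(abs(upsample_image(img, ir) - oracle_upsample(img, ir))), 1e-9)
  }
  # worked 2x2 example from the same oracle
  img <- matrix(c(0, 2, 1, 3), 2, 2)
  expect_lt(max(abs(upsample_image(img, 2) - oracle_upsample(img, 2))), 1e-12)
})

test_that("bilinear output range never exceeds the input range", {
  set.seed(21)
  for (i in 1:20) {
    img <- matrix(stats::runif(49, -50, 300), 7, 7)
    up <- upsample_image(img, sample(2:5, 1))
    expect_gte(min(up), min(img))
    expect_lte(max(up), max(img))
  }
})

test_that("upsample_mask replicates pixels into ir x ir blocks", {
  m <- matrix(c(1, 0, 0, 0), 2, 2, byrow = TRUE)
  up <- upsample_mask(m, 2)
  expect_identical(up, rbind(c(1, 1, 0, 0), c(1, 1, 0, 0),
                             c(0, 0, 0, 0), c(0, 0, 0, 0)))
  expect_identical(upsample_mask(m, 1), m)
  expect_error(upsample_mask(matrix(c(0, 2), 1, 2), 2), "binary")

  set.seed(22)
  for (i in 1:20) {
    ir <- sample(2:6, 1)
    m <- random_binary_matrix(sample(3:9, 1), sample(3:9, 1))
    up <- upsample_mask(m, ir)
    expect_true(all(up %in% c(0, 1)))
    expect_identical(sum(up), sum(m) * ir^2)  # exact foreground multiplication
  }
})

test_that("split_tiles produces the documented tile counts and shapes", {
  img <- matrix(0, 1024, 1024)
  ts <- split_tiles(img, 512)
  expect_length(ts$tiles, 4L)
  expect_identical(ts$grid$n_rows, 2L)
  expect_true(all(vapply(ts$tiles, function(t) identical(dim(t), c(512L, 512L)),
                         logical(1))))

  one <- split_tiles(matrix(1:25, 5, 5) * 1.0, 8)
  expect_length(one$tiles, 1L)
  expect_identical(one$grid$padded_shape, c(8L, 8L))
  # edge-replicate padding: last row of the pad equals the image's last row
  expect_identical(one$tiles[[1]][6:8, 1], rep(one$tiles[[1]][5, 1], 3))

  expect_identical(length(split_tiles(matrix(0, 4096, 4096), 512)$tiles), 64L)
})

test_that("merge_tiles inverts split_tiles bit-exactly, pads and all", {
  set.seed(23)
  for (i in 1:10) {
    h <- sample(5:120, 1); w <- sample(5:120, 1); tsz <- sample(c(8, 16, 32), 1)
    x <- matrix(stats::rnorm(h * w), h, w)
    expect_identical(merge_tiles(split_tiles(x, tsz)), x)
  }
  # row-major ordering: constant tiles 0..3 give a quadrant-constant canvas
  grid <- tile_grid(c(16L, 16L), 8L)
  ts <- structure(list(tiles = lapply(0:3, function(v) matrix(v, 8, 8)),
                       grid = grid, slice_index = 1L), class = "tile_set")
  canvas <- merge_tiles(ts)
  expect_identical(canvas[1, 16], 1)   # row 0, col 1 tile
  expect_identical(canvas[16, 1], 2)   # row 1, col 0 tile
  expect_identical(canvas[16, 16], 3)

  ts$tiles <- ts$tiles[1:3]
  expect_error(merge_tiles(ts), "tile count")
})

test_that("count_tiles and count_dataset_tiles reproduce the printed arithmetic", {
  expect_identical(count_tiles(512, 512, 2), 4L)
  expect_identical(count_tiles(512, 512, 8), 64L)
  expect_identical(count_tiles(512, 512, 1), 1L)
  expect_identical(count_tiles(100, 300, 3, 128), 3L * 8L)  # ceil(300/128)... ceil(900/128)=8, ceil(300/128)=3

  expect_equal(count_dataset_tiles(7552, 2), 30208)
  expect_equal(count_dataset_tiles(7552, c(1, 2, 4, 8)), 641920)
  expect_equal(count_dataset_tiles(3891, c(1, 2, 4, 8)), 330735)
})

test_that("downsample_nn inverts upsample_mask for every integer ratio", {
  set.seed(24)
  for (ir in 1:6) {
    m <- random_binary_matrix(sample(3:12, 1), sample(3:12, 1))
    expect_identical(downsample_nn(upsample_mask(m, ir), ir), m)
  }
  expect_identical(downsample_nn(matrix(1:16, 4, 4) * 1.0, 1), matrix(1:16, 4, 4) * 1.0)
  expect_error(downsample_nn(matrix(0, 5, 5), 2), "divisible")

  # quadrant-constant canvas samples the quadrant values
  canvas <- rbind(c(0, 0, 1, 1), c(0, 0, 1, 1), c(2, 2, 3, 3), c(2, 2, 3, 3))
  expect_identical(downsample_nn(canvas, 2), rbind(c(0, 1), c(2, 3)))
})

test_that("prepare_pair aligns image and mask tiles and conserves foreground", {
  set.seed(25)
  slice <- matrix(stats::runif(64 * 64, 0, 255), 64, 64)
  mask <- random_binary_matrix(64, 64, 0.2)
  pairs <- prepare_pair(slice, mask, interp_config(ir = 2, tile_size = 64))
  expect_length(pairs, 4L)
  fg <- sum(vapply(pairs, function(p) sum(p$mask), numeric(1)))
  expect_identical(fg, sum(mask) * 4)  # ir^2 conservation
  expect_identical(pairs[[2]]$row, 0L)
  expect_identical(pairs[[2]]$col, 1L)

  single <- prepare_pair(slice, mask, interp_config(ir = 1, tile_size = 64))
  expect_length(single, 1L)
  expect_identical(single[[1]]$image, slice)
  expect_identical(single[[1]]$mask, mask)
  expect_error(prepare_pair(slice, mask[1:32, ], interp_config(2, 64)), "dimensions")
})

test_that("reconstruct_prediction is the end-to-end inverse on masks", {
  set.seed(26)
  for (ir in c(1, 2, 4)) {
    m <- random_binary_matrix(32, 32)
    ts <- split_tiles(upsample_mask(m, ir), 32, ir = ir)
    expect_identical(reconstruct_prediction(ts, ir), m)
  }
  # all-ones tiles give an all-ones slice
  ts <- split_tiles(matrix(1, 64, 64), 32, ir = 2)
  expect_identical(reconstruct_prediction(ts, 2), matrix(1, 32, 32))
  # single bright tile confines foreground to the matching source quadrant
  ts <- split_tiles(matrix(0, 64, 64), 32, ir = 2)
  ts$tiles[[2]] <- matrix(1, 32, 32)  # row 0, col 1
  rec <- reconstruct_prediction(ts, 2)
  expect_identical(sum(rec[1:16, 17:32]), 256)
  expect_identical(sum(rec) - sum(rec[1:16, 17:32]), 0)
  # out-of-range probabilities are rejected
  ts$tiles[[1]][1, 1] <- 1.2
  expect_error(reconstruct_prediction(ts, 2), "\\[0, 1\\]")
})

test_that("tile export/import round-trips through the manifest", {
  set.seed(27)
  img <- matrix(sample(0:4095, 96 * 96, replace = TRUE), 96, 96)
  ts <- split_tiles(img, 32, ir = 2, slice_index = 7L)
  d <- withr::local_tempdir()
  manifest <- export_tiles(ts, d)
  back <- import_tiles(manifest)
  expect_identical(merge_tiles(back), img + 0)
  expect_identical(back$grid$n_rows, ts$grid$n_rows)
  expect_identical(back$slice_index, 7L)
})
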