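# segmenter backends, binarization, union, connected components

test_that("threshold_opening_backend is scale-sensitive on thin dark lines", {
  be <- threshold_opening_backend(tau = 55, opening_radius = 1)
  bright <- matrix(200, 64, 64)
  expect_identical(predict_tile(be, bright), matrix(0, 64, 64))

  # 2-pixel-wide dark line: removed by the diameter-3 element at ir = 1 ...
  tile <- matrix(200, 64, 64)
  tile[, 31:32] <- 0
  expect_identical(sum(predict_tile(be, tile)), 0)
  # ... retained once up-sampling widens it past the element diameter
  up <- upsample_image(tile, 2)
  expect_gt(sum(predict_tile(be, up)), 0)
  expect_error(threshold_opening_backend(tau = 300), "tau")
})

test_that("backend contract violations are caught by predict_tile", {
  bad_shape <- make_backend("bad", function(tile) tile[, 1:2, drop = FALSE])
  expect_error(predict_tile(bad_shape, matrix(0, 4, 4)), "shape")
  bad_range <- make_backend("bad", function(tile) tile * 0 + 2)
  expect_error(predict_tile(bad_range, matrix(0, 4, 4)), "\\[0, 1\\]")
  idb <- identity_backend()
  tile <- matrix(c(0, 51, 255), 3, 3)
  expect_equal(predict_tile(idb, tile), tile / 255)
  expect_identical(predict_tile(constant_backend(0), tile), matrix(0, 3, 3))
})

test_that("binary morphology: opening removes structures thinner than the element", {
  m <- matrix(0, 16, 16)
  m[5:12, 5:12] <- 1         # 8x8 block survives radius-2 opening
  m[2, 2] <- 1               # isolated pixel does not
  op <- binary_opening(m, 2)
  expect_identical(op[2, 2], 0)
  # opening a square by a disk rounds the corners: erosion leaves the 4x4
  # core, dilation restores the square minus 3 pixels per corner = 52
  expect_true(all(op <= m))
  expect_identical(sum(op), 52)
  expect_identical(binary_opening(m, 0), m)
  # erosion/dilation adjunction sanity on random masks
  set.seed(50)
  for (i in 1:5) {
    r <- random_binary_matrix(20, 20, 0.5)
    expect_true(all(binary_erode(r, 1) <= r))
    expect_true(all(binary_dilate(r, 1) >= r))
  }
})

test_that("binarize uses a strict threshold and is monotone", {
  half <- as_volume(array(0.5, c(2, 3, 3)))
  expect_identical(sum(binarize(half, 0.5)$data), 0)      # ties -> background
  bin <- as_volume(array(c(0, 1), c(2, 2, 2)))
  for (th in c(0.2, 0.5, 0.8)) {
    expect_identical(binarize(bin, th)$data, bin$data)
  }
  set.seed(51)
  prob <- as_volume(array(stats::runif(4^3), c(4, 4, 4)))
  expect_true(all(binarize(prob, 0.7)$data <= binarize(prob, 0.3)$data))
  expect_error(binarize(prob, 1), "threshold")
})

test_that("ensemble_union is a voxelwise OR with superset guarantee", {
  a <- array(0, c(2, 4, 4)); a[1, 1:3, 1] <- 1; a[2, 1, 1] <- 1; a[1, 4, 4] <- 1
  b <- array(0, c(2, 4, 4)); b[2, 2:4, 2] <- 1
  expect_identical(sum(a), 5); expect_identical(sum(b), 3)
  u <- ensemble_union(list(a, b))
  expect_identical(sum(u$data), 8)  # disjoint masks: 5 + 3
  expect_true(all(u$data >= a) && all(u$data >= b))
  expect_identical(ensemble_union(list(a))$data, a)
  expect_error(ensemble_union(list(a, b[1, , , drop = FALSE])), "shapes")
})

test_that("largest_connected_component picks the biggest component deterministically", {
  m <- array(0, c(3, 8, 8))
  m[2, 1:5, 1] <- 1                      # 5-voxel line
  m[2, 1:3, 8] <- 1                      # 3-voxel line
  lcc <- largest_connected_component(m)
  expect_identical(sum(lcc$data), 5)
  expect_identical(sum(lcc$data[2, 1:5, 1]), 5)

  # idempotent: a single component maps to itself
  expect_identical(largest_connected_component(lcc$data)$data, lcc$data)

  # connectivity matters: a diagonal pair is one component at 26, two at 6
  diag2 <- array(0, c(2, 2, 2)); diag2[1, 1, 1] <- 1; diag2[2, 2, 2] <- 1
  expect_identical(sum(largest_connected_component(diag2, 26)$data), 2)
  expect_identical(sum(largest_connected_component(diag2, 6)$data), 1)
  # equal sizes: the component containing the smallest voxel index wins
  expect_identical(which(largest_connected_component(diag2, 6)$data == 1),
                   which(diag2 == 1)[1])

  expect_warning(out <- largest_connected_component(array(0, c(2, 2, 2))), "empty")
  expect_identical(sum(out$data), 0)
})

test_that("largest component output is connected for random volumes", {
  set.seed(52)
  count_components <- function(mask, connectivity = 26L) {
    # independent flood fill for the test
    d <- dim(mask); seen <- array(FALSE, d); n <- 0L
    offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
    offs <- offs[rowSums(abs(offs)) > 0, ]
    if (connectivity == 6L) offs <- offs[rowSums(abs(offs)) == 1, ]
    for (seed in which(mask > 0)) {
      if (seen[seed]) next
      n <- n + 1L
      stack <- seed; seen[seed] <- TRUE
      while (length(stack)) {
        v <- stack[length(stack)]; stack <- stack[-length(stack)]
        co <- arrayInd(v, d)
        for (i in seq_len(nrow(offs))) {
          p <- co + offs[i, ]
          if (any(p < 1) || any(p > d)) next
          if (mask[p[1], p[2], p[3]] > 0 && !seen[p[1], p[2], p[3]]) {
            seen[p[1], p[2], p[3]] <- TRUE
            stack <- c(stack, (p[3] - 1) * d[1] * d[2] + (p[2] - 1) * d[1] + p[1])
          }
        }
      }
    }
    n
  }
  for (i in 1:5) {
    m <- array(stats::rbinom(6^3, 1, 0.25), c(6, 6, 6))
    if (sum(m) == 0) next
    lcc <- largest_connected_component(m, 26)
    expect_identical(count_components(lcc$data, 26), 1L)
    expect_true(all(lcc$data <= m))
  }
})

test_that("predict_volume honours the backend and validates outputs", {
  set.seed(53)
  v <- as_volume(array(stats::runif(4 * 32 * 32, 0, 255), c(4, 32, 32)))
  out <- predict_volume(v, identity_backend(), 1, 32)
  expect_equal(out$data, v$data / 255)
  expect_identical(sum(predict_volume(v, constant_backend(0), 2, 32)$data), 0)
  bad <- make_backend("bad", function(tile) tile)  # raw intensities > 1
  expect_error(predict_volume(v, bad, 1, 32), "\\[0, 1\\]")
})

test_that("up-scaling reveals terminal branches invisible at ir = 1", {
  fx <- scale_property_phantom()
  tp <- vapply(c(1, 4), function(ir) {
    pred <- binarize(predict_volume(fx$norm, fx$backend, ir, 64))
    sum(pred$data * fx$terminal_mask)
  }, numeric(1))
  expect_identical(tp[1], 0)  # sub-resolution terminals vanish at ir = 1
  expect_gt(tp[2], 0)         # and survive once magnified past the element
})
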