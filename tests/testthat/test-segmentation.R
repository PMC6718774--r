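test_that("stretch_contrast maps min/max to 0/1 and is idempotent", {
  expect_equal(stretch_contrast(matrix(c(2, 6, 4, 10), 2, 2)),
               matrix(c(0, 0.5, 0.25, 1), 2, 2))
  f <- matrix(c(0, 1, 0.3, 0.7), 2, 2)
  expect_equal(stretch_contrast(f), f)
  set.seed(1)
  g <- matrix(runif(100, 5, 9), 10, 10)
  s1 <- stretch_contrast(g)
  expect_true(all(s1 >= 0 & s1 <= 1))
  expect_equal(stretch_contrast(s1), s1)
})

test_that("a constant frame stretches to all zeros with a warning", {
  expect_warning(out <- stretch_contrast(matrix(7, 3, 3)), "Constant")
  expect_equal(out, matrix(0, 3, 3))
})

test_that("gaussian kernels are symmetric, normalized, radius ceil(3 sigma)", {
  for (sigma in c(0.5, 1, 2.7)) {
    w <- gaussian_kernel(sigma)
    expect_length(w, 2 * ceiling(3 * sigma) + 1)
    expect_equal(sum(w), 1)
    expect_equal(w, rev(w))
  }
  expect_error(gaussian_kernel(0), "positive")
  expect_error(gaussian_blur(matrix(1, 3, 3), -1), "positive")
})

test_that("blur preserves constants and reproduces the impulse response", {
  expect_equal(gaussian_blur(matrix(3.7, 9, 9), 2), matrix(3.7, 9, 9),
               tolerance = 1e-12)
  imp <- matrix(0, 33, 33)
  imp[17, 17] <- 1
  out <- gaussian_blur(imp, 2)
  w <- gaussian_kernel(2)
  expect_equal(out[(17 - 6):(17 + 6), (17 - 6):(17 + 6)], outer(w, w),
               tolerance = 1e-12)
})

test_that("separable blur equals direct 2-D convolution on random frames", {
  set.seed(42)
  f <- matrix(runif(32 * 32), 32, 32)
  for (sigma in c(1, 2)) {
    expect_lt(max(abs(gaussian_blur(f, sigma) - oracle_conv2(f, sigma))), 1e-9)
  }
})

test_that("DoG is zero for equal sigmas, linear, and positive on a bright disk", {
  set.seed(3)
  f <- matrix(runif(400), 20, 20)
  g <- matrix(runif(400), 20, 20)
  expect_equal(dog_filter(f, 2, 2), matrix(0, 20, 20), tolerance = 1e-12)
  expect_lt(max(abs(dog_filter(f + g, 2, 5) -
                      (dog_filter(f, 2, 5) + dog_filter(g, 2, 5)))), 1e-9)
  disk <- matrix(0, 41, 41)
  rows <- matrix(1:41, 41, 41)
  disk[(rows - 21)^2 + (t(rows) - 21)^2 <= 16] <- 1
  expect_gt(dog_filter(disk, 2, 6)[21, 21], 0)
})

test_that("thresholding is strict: pixels equal to th are background", {
  expect_false(any(threshold_binary(matrix(0, 4, 4), 0.1)))
  expect_true(all(threshold_binary(matrix(1, 4, 4), 0.5)))
  m <- matrix(c(0.1, 0.10000001, 0.099), 1, 3)
  expect_equal(as.vector(threshold_binary(m, 0.1)), c(FALSE, TRUE, FALSE))
})

test_that("connected components: gaps split, diagonal adjacency depends on connectivity", {
  m <- matrix(FALSE, 8, 8)
  m[1:3, 1:3] <- TRUE
  m[1:3, 6:8] <- TRUE
  expect_equal(nrow(label_components(m)), 2)

  diag2 <- matrix(FALSE, 4, 4)
  diag2[1, 1] <- diag2[2, 2] <- TRUE
  expect_equal(nrow(label_components(diag2, connectivity = 4)), 2)
  expect_equal(nrow(label_components(diag2, connectivity = 8)), 1)
})

test_that("labeling partitions the mask: ROI pixels plus dropped small clusters", {
  set.seed(11)
  for (i in 1:10) {
    mask <- matrix(runif(900) < 0.35, 30, 30)
    rois <- label_components(mask, connectivity = 8, min_size_px = 3)
    all_rois <- label_components(mask, connectivity = 8, min_size_px = 1)
    kept <- unlist(roi_set_partition(rois))
    everything <- unlist(roi_set_partition(all_rois))
    expect_setequal(everything, which(mask))
    expect_true(all(kept %in% which(mask)))
    expect_true(all(rois$area_px >= 3))
  }
})

test_that("labeling agrees with a flood-fill oracle as a partition", {
  set.seed(5)
  for (i in 1:10) {
    mask <- matrix(runif(625) < 0.4, 25, 25)
    for (conn in c(4L, 8L)) {
      expect_identical(roi_set_partition(label_components(mask, conn)),
                       as_partition(oracle_flood_labels(mask, conn)))
    }
  }
})

test_that("ROI centroids are pixel-coordinate means and areas the pixel counts", {
  m <- matrix(FALSE, 6, 6)
  m[2:3, 2:4] <- TRUE
  rois <- label_components(m)
  expect_equal(rois$centroid_row, 2.5)
  expect_equal(rois$centroid_col, 3)
  expect_equal(rois$area_px, 6L)
})

test_that("detect_rois finds nothing on a blank frame and is monotone in th", {
  stack <- image_stack(array(0, c(16, 16, 1)))
  expect_warning(rois <- detect_rois(stack, 1), "Constant")
  expect_equal(nrow(rois), 0)

  mv <- generate_movie(synthetic_preset("segmentation", seed = 3))
  frame <- get_frame(mv$stack, 1)
  ths <- c(0.02, 0.1, 0.3, 1.0)
  counts <- vapply(ths, function(th) {
    nrow(detect_rois(mv$stack, 1, segmentation_params(th = th)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[length(counts)], 0)
})

test_that("detection is invariant to positive rescaling of the frame", {
  mv <- generate_movie(synthetic_preset("segmentation", seed = 2))
  p <- segmentation_params()
  base <- detect_rois(mv$stack, 1, p)
  for (c in c(0.001, 7, 1e4)) {
    scaled <- detect_rois(get_frame(mv$stack, 1) * c, params = p)
    expect_identical(as_label_matrix(scaled), as_label_matrix(base))
  }
})

test_that("manual edits remove, add, and restore disjointness", {
  m <- matrix(FALSE, 10, 10)
  m[2:4, 2:4] <- TRUE
  auto <- label_components(m)

  expect_equal(nrow(merge_manual_rois(auto, remove = 1L)), 0)
  expect_error(merge_manual_rois(auto, remove = 99L), "Unknown")

  add <- matrix(FALSE, 10, 10)
  add[7:8, 7:8] <- TRUE
  grown <- merge_manual_rois(roi_set(list(), c(10, 10)), add = add)
  expect_equal(nrow(grown), 1)
  expect_equal(grown$area_px, 4L)

  # overlapping manual ROI eats into the automatic one
  overlap <- matrix(FALSE, 10, 10)
  overlap[3:5, 3:5] <- TRUE
  merged <- merge_manual_rois(auto, add = overlap)
  expect_equal(nrow(merged), 2)
  lab <- as_label_matrix(merged)
  expect_equal(sum(lab > 0), sum(m | overlap))
  auto_left <- merged$area_px[1]
  expect_equal(auto_left, sum(m) - sum(m & overlap))
})
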