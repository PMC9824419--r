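test_that("white/dark calibration reproduces the reflectance identities", {
  d <- c(3L, 2L, 2L)
  wl <- c(680, 800)
  white <- array(220, d); dark <- array(20, d)
  refs <- reference_pair(white, dark)

  same_as_white <- hsi_cube(white, wl)
  expect_equal(white_calibrate(same_as_white, refs)$data, array(1, d))
  same_as_dark <- hsi_cube(dark, wl)
  expect_equal(white_calibrate(same_as_dark, refs)$data, array(0, d))

  raw <- hsi_cube(array(120, d), wl)
  cal <- white_calibrate(raw, refs)
  expect_equal(cal$data[2, 1, 2], (120 - 20) / (220 - 20)) # 0.5
  expect_identical(cal$kind, "reflectance")
})

test_that("a cols x bands reference strip is accepted and replicated", {
  d <- c(5L, 3L, 2L)
  raw <- hsi_cube(array(seq_len(prod(d)), d), c(680, 800))
  white <- matrix(200, d[2], d[3]); dark <- matrix(10, d[2], d[3])
  cal <- white_calibrate(raw, reference_pair(white, dark))
  expect_equal(cal$data, (raw$data - 10) / 190)
})

test_that("calibrating twice is rejected and degenerate references are handled", {
  d <- c(2L, 2L, 2L)
  refl <- hsi_cube(array(0.5, d), c(680, 800), kind = "reflectance")
  refs <- reference_pair(array(2, d), array(1, d))
  expect_error(white_calibrate(refl, refs), class = "leafcal_state_error")

  raw <- hsi_cube(array(1.5, d), c(680, 800))
  white <- array(2, d); white[1, 1, 1] <- 1 # white == dark there
  expect_error(
    white_calibrate(raw, reference_pair(white, array(1, d)),
                    on_degenerate = "error"),
    "band 1", class = "leafcal_degenerate_error")
  expect_warning(
    cal <- white_calibrate(raw, reference_pair(white, array(1, d))),
    "marking invalid")
  expect_true(is.na(cal$data[1, 1, 1]))
  expect_equal(cal$data[2, 2, 2], 0.5)
})

test_that("band lookup picks the nearest center and reports it", {
  cube <- hsi_cube(array(1, c(1, 1, 3)), c(400, 500, 600))
  expect_identical(attr(band_at(cube, 500), "band"), 2L)
  cube2 <- hsi_cube(array(1, c(1, 1, 3)), c(679.1, 680.2, 681.3))
  expect_equal(attr(band_at(cube2, 680), "wavelength"), 680.2)
  expect_error(band_at(cube, 300), class = "leafcal_range_error")
  expect_error(band_at(cube, 601), class = "leafcal_range_error")
})

test_that("red-edge segmentation thresholds the normalized index", {
  cube <- flat_cube(2, 2)
  cube$data[1, 1, 2] <- 0.05; cube$data[1, 1, 3] <- 0.45 # index 0.8
  cube$data[2, 2, 2] <- 0.30; cube$data[2, 2, 3] <- 0.30 # index 0
  m <- segment_leaf(cube, threshold = 0.5)
  expect_true(m[1, 1])
  expect_false(m[2, 2])
  # equal bands give index 0: background at any positive threshold
  expect_false(segment_leaf(cube, threshold = 1e-6)[2, 2])
})

test_that("auto threshold isolates injected leaf pixels in a background cube", {
  bg <- array(rep(c(0.25, 0.25, 0.25, 0.25, 0.25), each = 64), c(8, 8, 5))
  cube <- hsi_cube(bg, c(560, 680, 732, 800, 900), kind = "reflectance")
  cube$data[3, 4, 2] <- 0.05; cube$data[3, 4, 3] <- 0.45
  cube$data[6, 7, 2] <- 0.06; cube$data[6, 7, 3] <- 0.40
  m <- segment_leaf(cube, threshold = "auto")
  leaf_idx <- c(3L + (4L - 1L) * 8L, 6L + (7L - 1L) * 8L)
  expect_identical(sort(which(m)), leaf_idx)
  # brute force: every threshold between the two histogram modes separates
  # exactly these two pixels, so the auto split must land there
  idx01 <- (cube$data[, , 3] - cube$data[, , 2]) /
    (cube$data[, , 3] + cube$data[, , 2])
  expect_gt(attr(m, "threshold"), max(idx01[-leaf_idx]))
  expect_lt(attr(m, "threshold"), min(idx01[leaf_idx]))
})

test_that("segmentation is monotone in the threshold", {
  set.seed(42)
  cube <- flat_cube(10, 10)
  cube$data[, , 2] <- matrix(runif(100, 0.02, 0.4), 10)
  cube$data[, , 3] <- matrix(runif(100, 0.02, 0.5), 10)
  thresholds <- seq(-0.5, 0.9, by = 0.1)
  masks <- lapply(thresholds, function(t) segment_leaf(cube, t))
  for (i in seq_along(masks)[-1])
    expect_true(all(masks[[i]] <= masks[[i - 1]]))
})

test_that("NDVI reproduces hand values and stays in [-1, 1]", {
  cube <- flat_cube(2, 2)
  cube$data[1, 1, 2] <- 0.1; cube$data[1, 1, 4] <- 0.8
  cube$data[1, 2, 2] <- 0.3; cube$data[1, 2, 4] <- 0.3
  cube$data[2, 1, 2] <- 0.0; cube$data[2, 1, 4] <- 0.4
  nd <- compute_ndvi(cube)
  expect_equal(nd[1, 1], 0.7 / 0.9)
  expect_equal(nd[1, 2], 0)
  expect_equal(nd[2, 1], 1) # RED = 0: bound attained

  set.seed(7)
  rnd <- flat_cube(6, 6)
  rnd$data[, , 2] <- matrix(runif(36, 0, 2), 6)
  rnd$data[, , 4] <- matrix(runif(36, 0, 2), 6)
  v <- compute_ndvi(rnd)
  expect_true(all(v[!is.na(v)] >= -1 & v[!is.na(v)] <= 1))
})

test_that("NDVI is invariant to a common positive scaling of RED and NIR", {
  set.seed(8)
  cube <- flat_cube(5, 5)
  cube$data[, , 2] <- matrix(runif(25, 0.01, 0.5), 5)
  cube$data[, , 4] <- matrix(runif(25, 0.01, 0.9), 5)
  scaled <- cube
  scaled$data <- scaled$data * 3.7
  expect_equal(unclass(compute_ndvi(cube)), unclass(compute_ndvi(scaled)),
               tolerance = 1e-12)
})

test_that("NDVI guards: near-zero denominator invalid, masks respected", {
  cube <- flat_cube(2, 2)
  cube$data[1, 1, 2] <- 0; cube$data[1, 1, 4] <- 0
  mask <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  nd <- compute_ndvi(cube, mask)
  expect_true(is.na(nd[1, 1])) # NIR + RED below guard
  expect_true(is.na(nd[2, 2])) # masked out
  expect_false(is.na(nd[2, 1]))
  raw <- flat_cube(2, 2, kind = "raw")
  expect_error(compute_ndvi(raw), class = "leafcal_state_error")
  skinny <- hsi_cube(array(0.2, c(2, 2, 2)), c(680, 700), "reflectance")
  expect_error(compute_ndvi(skinny), class = "leafcal_coverage_error")
})

test_that("mean NDVI averages valid pixels only", {
  m <- matrix(NA_real_, 2, 2)
  m[1, 1] <- 0.2; m[2, 2] <- 0.4
  expect_equal(mean_ndvi(ndvi_map(m)), 0.3)
  single <- matrix(c(0.55, NA, NA, NA), 2, 2)
  expect_equal(mean_ndvi(ndvi_map(single)), 0.55)

  set.seed(9)
  v <- runif(100, -1, 1)
  big <- ndvi_map(matrix(v, 10, 10))
  acc <- 0
  for (x in v) acc <- acc + x # independent summation oracle
  expect_equal(mean_ndvi(big), acc / 100, tolerance = 1e-12)

  expect_error(mean_ndvi(ndvi_map(matrix(NA_real_, 2, 2))),
               class = "leafcal_empty_error")
})
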