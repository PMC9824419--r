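test_that("ratio tables divide by the 0-degree reference", {
  rec <- tibble::tibble(
    leaf_id = "a", species = "soybean", orientation_deg = 0,
    angle_deg = c(0, 30), mean_ndvi = c(0.80, 0.84))
  tab <- build_ratio_table(rec)
  expect_equal(tab$ratio, c(1, 1.05))

  const <- tibble::tibble(
    leaf_id = "b", species = "soybean",
    orientation_deg = rep(c(0, 45), each = 9),
    angle_deg = rep(seq(0, 80, 10), 2), mean_ndvi = 0.77)
  expect_true(all(build_ratio_table(const)$ratio == 1))

  missing0 <- rec[rec$angle_deg != 0, ]
  expect_error(build_ratio_table(missing0), class = "leafcal_state_error")
})

test_that("per-orientation and per-leaf references differ as documented", {
  rec <- tibble::tibble(
    leaf_id = "a", species = "corn",
    orientation_deg = rep(c(0, 45), each = 2),
    angle_deg = rep(c(0, 30), 2), mean_ndvi = c(0.8, 0.88, 0.9, 0.99))
  per_or <- build_ratio_table(rec, "per-orientation")
  expect_equal(per_or$ratio[per_or$angle_deg == 0], c(1, 1))
  per_leaf <- build_ratio_table(rec, "per-leaf")
  expect_equal(per_leaf$ratio, rec$mean_ndvi / 0.85)
})

test_that("venetian blinds interleave folds across the ordered samples", {
  f <- venetian_folds(12, 5)
  expect_equal(f, c(1, 2, 3, 4, 5, 1, 2, 3, 4, 5, 1, 2))
  expect_error(venetian_folds(10, 1), class = "leafcal_parameter_error")
})

test_that("SVR recovers a noiseless ratio surface almost perfectly", {
  prof <- species_profile("soybean")
  rec <- simulate_rotation_experiment(prof, 4, sigma = 0, baseline_sd = 0,
                                      seed = 50)
  fm <- fit_ratio_model(build_ratio_table(rec))
  expect_gte(fm$cv_r2, 0.99)
})

test_that("pure-noise ratios carry no predictable structure", {
  set.seed(51)
  grid <- expand.grid(angle_deg = seq(0, 80, 10),
                      orientation_deg = seq(0, 315, 45))
  tab <- tibble::tibble(angle_deg = rep(grid$angle_deg, 4),
                        orientation_deg = rep(grid$orientation_deg, 4),
                        ratio = rnorm(288, 1, 0.05))
  fm <- fit_ratio_model(tab)
  expect_lte(fm$cv_r2, 0.1)
})

test_that("degenerate single-level predictors are rejected", {
  tab <- tibble::tibble(angle_deg = rep(30, 20), orientation_deg = rep(0, 20),
                        ratio = rnorm(20, 1, 0.01))
  expect_error(fit_ratio_model(tab), class = "leafcal_degenerate_error")
})

test_that("predictions anchor near 1 at zero tilt and are periodic in alpha", {
  rec <- simulate_rotation_experiment(species_profile("corn"), 6,
                                      sigma = 0.01, seed = 52)
  fm <- fit_ratio_model(build_ratio_table(rec))
  expect_equal(predict_ratio(fm, 0, 135), 1, tolerance = 0.02)
  a <- seq(0, 315, 45)
  expect_equal(predict_ratio(fm, rep(40, 8), a),
               predict_ratio(fm, rep(40, 8), a + 360), tolerance = 1e-12)
  expect_warning(predict_ratio(fm, 85, 0), "extrapolation")
})

test_that("prediction equals the direct kernel-sum expansion over support vectors", {
  rec <- simulate_rotation_experiment(species_profile("soybean"), 3,
                                      sigma = 0.01, seed = 53)
  tab <- build_ratio_table(rec)
  fm <- fit_ratio_model(tab)
  th <- tab$angle_deg[1:40]; al <- tab$orientation_deg[1:40]
  pred <- predict_ratio(fm, th, al)
  # independent oracle: explicit RBF expansion sum_i coef_i K(sv_i, x) - rho
  X <- leafcal:::encode_features(th, al %% 360, enc = fm$encoding)$X
  oracle <- vapply(seq_len(nrow(X)), function(i) {
    k <- exp(-fm$hyper$gamma * colSums((t(fm$sv$SV) - X[i, ])^2))
    sum(fm$sv$coefs * k) - fm$sv$rho
  }, numeric(1))
  expect_equal(pred, oracle, tolerance = 1e-9)
})

test_that("species-specific models keep their distinct peak angles", {
  peaks <- vapply(c("soybean", "corn"), function(sp) {
    rec <- simulate_rotation_experiment(species_profile(sp), 6, sigma = 0.01,
                                        seed = 54)
    fm <- fit_ratio_model(build_ratio_table(rec))
    th <- seq(0, 80, 1)
    th[which.max(marginal_ratio(fm, th))]
  }, numeric(1))
  expect_true(peaks["soybean"] >= 25 && peaks["soybean"] <= 35)
  expect_true(peaks["corn"] >= 45 && peaks["corn"] <= 55)
})

test_that("3D calibration divides NDVI by the predicted ratio", {
  rec <- simulate_rotation_experiment(species_profile("corn"), 6,
                                      sigma = 0.005, seed = 55)
  fm <- fit_ratio_model(build_ratio_table(rec))

  nd <- ndvi_map(matrix(0.84, 3, 3))
  ang <- structure(list(theta = matrix(40, 3, 3),
                        alpha = matrix(90, 3, 3),
                        valid = matrix(TRUE, 3, 3)), class = "angle_map")
  out <- apply_3d_calibration(nd, ang, fm)
  r <- predict_ratio(fm, 40, 90)
  expect_equal(out[2, 2], 0.84 / r, tolerance = 1e-12)
  # hand-division check at an exact ratio of 1.05
  expect_equal(0.84 / 1.05, 0.80)

  # flat map: ratio ~ 1, output ~ input
  flat_ang <- structure(list(theta = matrix(0, 3, 3),
                             alpha = matrix(NA_real_, 3, 3),
                             valid = matrix(TRUE, 3, 3)), class = "angle_map")
  flat_out <- apply_3d_calibration(nd, flat_ang, fm)
  expect_equal(unclass(flat_out), unclass(nd), tolerance = 0.02)

  bad_ang <- structure(list(theta = matrix(0, 2, 2),
                            alpha = matrix(NA_real_, 2, 2),
                            valid = matrix(TRUE, 2, 2)), class = "angle_map")
  expect_error(apply_3d_calibration(nd, bad_ang, fm),
               class = "leafcal_dimension_error")
})

test_that("calibration with oracle ratios recovers flat-leaf NDVI on scenes", {
  prof <- species_profile("corn")
  sc <- make_leaf_scene(prof, list(type = "arch"), sigma = 0.005,
                        acq_sigma = 0, seed = 56)
  nd <- compute_ndvi(sc$cube)
  leaf <- sc$truth$leaf
  # divide by the generator's true ratio instead of the SVR prediction
  recovered <- unclass(nd) / sc$truth$ratio
  err <- abs(recovered - sc$truth$flat_ndvi)[leaf]
  expect_lt(mean(err), 0.01) # at the sensor-noise level
  uncal_err <- abs(unclass(nd) - sc$truth$flat_ndvi)[leaf]
  expect_lt(mean(err), mean(uncal_err))
})

test_that("end-to-end 3D calibration moves NDVI toward the flat truth", {
  prof <- species_profile("corn")
  wins <- vapply(1:3, function(s) {
    pe <- suppressWarnings(protocol_experiment(profile = prof, seed = s))
    pe$d_calibrated3d < pe$d_practical
  }, logical(1))
  expect_true(all(wins))
})
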