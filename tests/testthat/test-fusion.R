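make_model <- function(M, model = "pushbroom") {
  structure(list(M = M, model = model, gauge = "norm_m3_spatial", cheb = NULL,
                 fit_stats = NULL, rms = 0), class = "projection_model")
}

random_volume_points <- function(n, seed) {
  set.seed(seed)
  data.frame(x = runif(n, 0, 0.2), y = runif(n, 0, 0.2),
             z = sample(c(0, 0.05), n, replace = TRUE))
}

test_that("DLT recovers a noiseless pushbroom camera to < 1e-6 px", {
  sc <- make_checkerboard_scene()
  fit <- solve_projection(sc$correspondences)
  expect_lt(max(abs(fit$fit_stats$du), abs(fit$fit_stats$dv)), 1e-6)
  # 100 held-out points across the working volume
  held <- random_volume_points(100, seed = 31)
  truth <- project(sc$truth$model, held$x, held$y, held$z)
  pred <- project(fit, held$x, held$y, held$z)
  expect_lt(max(abs(pred$u - truth$u), abs(pred$v - truth$v)), 1e-6)
})

test_that("the fully projective variant recovers a projective camera", {
  cam <- make_model(rbind(c(900, 30, -20, 5), c(10, 950, 40, 8),
                          c(0.05, 0.08, -1, 0.7) /
                            sqrt(sum(c(0.05, 0.08, -1)^2))),
                    model = "projective")
  pts <- random_volume_points(13, seed = 35)
  pr <- project(cam, pts$x, pts$y, pts$z)
  fit <- solve_projection(cbind(u = pr$u, v = pr$v, pts),
                          model = "projective")
  expect_lt(max(abs(fit$fit_stats$du), abs(fit$fit_stats$dv)), 1e-6)
  held <- random_volume_points(100, seed = 36)
  truth <- project(cam, held$x, held$y, held$z)
  pred <- project(fit, held$x, held$y, held$z)
  expect_lt(max(abs(pred$u - truth$u), abs(pred$v - truth$v)), 1e-6)
})

test_that("DLT rejects too few or degenerate correspondences", {
  sc <- make_checkerboard_scene()
  expect_error(solve_projection(sc$correspondences[1:6, ]),
               class = "leafcal_degenerate_error")
  flat <- sc$correspondences
  flat$z <- 0.02 # all points on one height layer
  expect_error(solve_projection(flat), class = "leafcal_degenerate_error")
})

test_that("an identity-like model projects points to themselves", {
  M <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 0, 1))
  m <- make_model(M)
  pr <- project(m, 3.0, 4.0, 0.7)
  expect_equal(pr$u, 3.0)
  expect_equal(pr$v, 4.0)
  expect_error(project(make_model(rbind(c(1, 0, 0, 0), c(0, 1, 0, 0),
                                        c(0, 0, 1, 0))), 1, 1, 0),
               class = "leafcal_degenerate_error") # w = 0
})

test_that("fit_stats agree with re-projection at the fitting points", {
  sc <- make_checkerboard_scene(noise = "quantize", seed = 12)
  fit <- solve_projection(sc$correspondences)
  pr <- project(fit, sc$correspondences$x, sc$correspondences$y,
                sc$correspondences$z)
  expect_equal(fit$fit_stats$du, pr$u - sc$correspondences$u,
               tolerance = 1e-12)
  expect_equal(fit$fit_stats$dv, pr$v - sc$correspondences$v,
               tolerance = 1e-12)
})

test_that("the stored matrix satisfies the scale gauge and projection is gauge-free", {
  sc <- make_checkerboard_scene(seed = 3)
  fit <- solve_projection(sc$correspondences)
  expect_equal(sqrt(sum(fit$M[3, 1:3]^2)), 1, tolerance = 1e-12)
  # the projective variant is invariant to a global rescaling of M
  fitp <- solve_projection(sc$correspondences, model = "projective")
  scaled <- fitp; scaled$M <- fitp$M * -3.7
  held <- random_volume_points(50, seed = 32)
  expect_equal(project(scaled, held$x, held$y, held$z),
               project(fitp, held$x, held$y, held$z), tolerance = 1e-9)
  # for the pushbroom form the freedom is in (m2, m3) jointly
  fit2 <- fit; fit2$M[2:3, ] <- fit$M[2:3, ] * 2.5
  expect_equal(project(fit2, held$x, held$y, held$z),
               project(fit, held$x, held$y, held$z), tolerance = 1e-9)
})

test_that("Chebyshev refinement: zero residuals give zero coefficients", {
  sc <- make_checkerboard_scene()
  fit <- solve_projection(sc$correspondences)
  ref <- chebyshev_refine(fit, sc$correspondences)
  expect_lt(max(abs(ref$cheb$coef_u)), 1e-6)
  expect_lt(max(abs(ref$cheb$coef_v)), 1e-6)
})

test_that("Chebyshev refinement interpolates an exact degree-3 surface", {
  sc <- make_checkerboard_scene()
  base <- solve_projection(sc$correspondences)
  pts <- random_volume_points(40, seed = 33)
  pr <- project(base, pts$x, pts$y, pts$z)
  # distort observations by a known degree-3 Chebyshev surface in (u, v)
  box <- list(u = range(pr$u), v = range(pr$v))
  nn <- leafcal:::cheb_normalize(pr$u, pr$v, box)
  B <- leafcal:::cheb_basis(nn$un, nn$vn, 3L)
  cu <- c(0.5, -1, 2, 0.3, 1, -0.7, 0.2, 0.1, -0.4, 0.05)
  cv <- rev(cu)
  obs <- data.frame(u = pr$u + B %*% cu, v = pr$v + B %*% cv,
                    x = pts$x, y = pts$y, z = pts$z)
  # direct linear-solve oracle: the basis can represent the surface exactly,
  # so refined residuals must vanish
  ref <- chebyshev_refine(base, obs)
  expect_lt(max(abs(ref$fit_stats$du), abs(ref$fit_stats$dv)), 1e-9)
  expect_lt(ref$rms, 1e-9)
})

test_that("Chebyshev refinement never increases the fitting RMS", {
  set.seed(34)
  for (rep in 1:5) {
    sc <- make_checkerboard_scene()
    pts <- random_volume_points(30, seed = 40 + rep)
    pr <- project(sc$truth$model, pts$x, pts$y, pts$z)
    obs <- data.frame(u = pr$u + rnorm(30, 0, 1), v = pr$v + rnorm(30, 0, 1),
                      x = pts$x, y = pts$y, z = pts$z)
    fit <- solve_projection(obs)
    ref <- chebyshev_refine(fit, obs)
    expect_lte(ref$rms, fit$rms + 1e-12)
  }
  expect_error(
    chebyshev_refine(solve_projection(make_checkerboard_scene()$correspondences),
                     make_checkerboard_scene()$correspondences[1:9, ]),
    class = "leafcal_degenerate_error")
})

test_that("fusing a flat cloud yields a constant height field with exact grid hits", {
  # integer-resolution camera: at z = 0.005 (w = 0.625) the cloud points
  # project exactly onto integer pixels (u = 1000x + 10, v = 500y + 10)
  cam <- make_model(rbind(c(1000, 0, 0, 10), c(0, 312.5, 0, 6.25),
                          c(0, 0, -1, 0.63)))
  g <- seq(0, 0.04, by = 0.002)
  X <- matrix(rep(g, length(g)), length(g), length(g))
  Y <- matrix(rep(g, each = length(g)), length(g), length(g))
  cloud <- point_cloud(X, Y, X * 0 + 0.005)
  fg <- fuse(cam, cloud, c(64L, 64L))
  expect_true(any(fg$valid))
  expect_equal(range(fg$z[fg$valid]), c(0.005, 0.005), tolerance = 1e-12)
  # pixels coinciding with projected cloud points carry the cloud's x
  pr <- project(cam, as.numeric(X), as.numeric(Y), as.numeric(X * 0 + 0.005))
  hits <- which(abs(pr$u - round(pr$u)) < 1e-9 & abs(pr$v - round(pr$v)) < 1e-9 &
                  pr$u >= 0 & pr$v >= 0 & pr$u < 64 & pr$v < 64)
  lin <- round(pr$u[hits]) + 1L + round(pr$v[hits]) * 64L
  on_grid <- fg$valid[lin]
  expect_true(any(on_grid))
  expect_equal(fg$x[lin][on_grid], as.numeric(X)[hits][on_grid],
               tolerance = 1e-9)
})

test_that("fusing a cloud that misses the image raises an empty-overlap error", {
  cam <- make_model(rbind(c(1000, 0, 0, 0), c(0, 1260, 0, 0),
                          c(0, 0, -1, 0.63)))
  g <- seq(-0.5, -0.45, by = 0.005) # far outside the image footprint
  X <- matrix(rep(g, length(g)), length(g), length(g))
  Y <- t(X)
  expect_error(fuse(cam, point_cloud(X, Y, X * 0), c(64L, 64L)),
               class = "leafcal_empty_error")
})

test_that("an arched-leaf scene fuses geometry onto >= 95% of leaf pixels", {
  sc <- make_leaf_scene(species_profile("corn"), list(type = "arch"),
                        sigma = 0, acq_sigma = 0, seed = 13)
  pm <- solve_projection(sc$correspondences)
  fg <- fuse(pm, sc$cloud, dim(sc$cube)[1:2])
  expect_gte(mean(fg$valid[sc$truth$leaf]), 0.95)
})

test_that("pixel resolutions match the system's printed geometry", {
  expect_equal(round(pixel_resolution(1886, 200), 4), 0.1060)
  expect_equal(round(pixel_resolution(782, 200), 4), 0.2558)
  expect_equal(pixel_resolution(200, 200), 1.0)
  expect_error(pixel_resolution(0, 200), class = "leafcal_value_error")
  expect_error(pixel_resolution(200, -1), class = "leafcal_value_error")
})

test_that("corner mismatch bookkeeping summarizes printed detections", {
  path <- system.file("extdata", "checkerboard_corners.csv",
                      package = "leafcal")
  tab <- read.csv(path)
  # mm conversions use the resolutions at their reported 4-digit precision
  mm <- corner_mismatch(tab,
                        res_row_mm = round(pixel_resolution(1886, 200), 4),
                        res_col_mm = round(pixel_resolution(782, 200), 4))
  expect_equal(mm$max_row_px, 3)
  expect_equal(mm$max_col_px, 2)
  expect_equal(mm$max_row_mm, 0.3180)
  expect_equal(mm$max_col_mm, 0.5116)
})
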