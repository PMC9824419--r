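#' Estimate the pushbroom projection matrix from corner correspondences
#'
#' Solves the 3x4 projection `M` mapping depth-camera ground coordinates
#' `(x, y, z)` to hyperspectral pixel coordinates `(u, v)` by direct linear
#' transformation (DLT) least squares. Two model forms are supported:
#'
#' * `"pushbroom"` (default, the linear pushbroom convention): the scan-axis
#'   row is affine, `u = m11 x + m12 y + m13 z + m14`, while the column is
#'   perspective within the scan line, `v = (m2 . X) / (m3 . X)`.
#' * `"projective"`: a fully projective camera,
#'   `u = (m1 . X) / (m3 . X)`, `v = (m2 . X) / (m3 . X)`.
#'
#' The DLT scale gauge is fixed by `||(m31, m32, m33)|| = 1` with the sign
#' chosen so the homogeneous denominator is positive at the fitting centroid
#' (falling back to `m34 = 1` when the spatial part of the third row
#' vanishes, i.e. an affine column).
#'
#' @param points data frame of correspondences with columns `u, v, x, y, z`
#'   (pixels, pixels, meters); at least 7 rows spanning more than one height
#'   layer.
#' @param model `"pushbroom"` or `"projective"`.
#' @return A `projection_model`: list with the 3x4 matrix `M`, `model`,
#'   `gauge`, `cheb` (`NULL` until [chebyshev_refine()]), a `fit_stats` tibble
#'   of signed per-point residuals `(du, dv)` and the fitting `rms`.
#' @export
solve_projection <- function(points, model = c("pushbroom", "projective")) {
  model <- match.arg(model)
  points <- tibble::as_tibble(points)
  need <- c("u", "v", "x", "y", "z")
  if (!all(need %in% names(points)))
    lc_abort("correspondences need columns u,v,x,y,z.", "dimension_error")
  n <- nrow(points)
  if (n < 7L)
    lc_abort(sprintf("need at least 7 correspondences, got %d.", n),
             "degenerate_error")
  X <- cbind(points$x, points$y, points$z, 1)
  # rank of the ground configuration: a single height layer (or any affine
  # dependency among x,y,z,1) leaves the DLT system underdetermined
  sv <- svd(scale(X, center = FALSE, scale = c(stats::sd(points$x) + 1e-12,
                                               stats::sd(points$y) + 1e-12,
                                               stats::sd(points$z) + 1e-12, 1)))$d
  if (sv[4L] / sv[1L] < 1e-8)
    lc_abort(paste("degenerate correspondence configuration:",
                   "ground points are affinely dependent",
                   "(e.g., all on one height layer)."), "degenerate_error")

  homog_row <- function(target) {
    # rows of the homogeneous system [X, -target*X] (m_k; m3) = 0
    A <- cbind(X, -target * X)
    s <- svd(A)
    v <- s$v[, 8L]
    if (s$d[7L] / s$d[1L] < 1e-10)
      lc_abort("DLT system is rank-deficient for this configuration.",
               "degenerate_error")
    v
  }

  if (model == "pushbroom") {
    m1 <- qr.solve(X, points$u)
    sol <- homog_row(points$v)
    m2 <- sol[1:4]; m3 <- sol[5:8]
  } else {
    # fully projective: stack both pixel constraint sets with a shared
    # third row and take the SVD null vector of the 2n x 12 system
    A <- rbind(cbind(X, matrix(0, n, 4), -points$u * X),
               cbind(matrix(0, n, 4), X, -points$v * X))
    s <- svd(A)
    if (s$d[11L] / s$d[1L] < 1e-10)
      lc_abort("DLT system is rank-deficient for this configuration.",
               "degenerate_error")
    v12 <- s$v[, 12L]
    m1 <- v12[1:4]; m2 <- v12[5:8]; m3 <- v12[9:12]
  }

  # gauge fixing
  s3 <- sqrt(sum(m3[1:3]^2))
  if (s3 > 1e-12) {
    g <- 1 / s3
    gauge <- "norm_m3_spatial"
  } else {
    g <- 1 / m3[4L]
    gauge <- "affine"
  }
  m2 <- m2 * g; m3 <- m3 * g
  if (model == "projective") m1 <- m1 * g
  cen <- c(mean(points$x), mean(points$y), mean(points$z), 1)
  if (sum(m3 * cen) < 0) {
    m2 <- -m2; m3 <- -m3
    if (model == "projective") m1 <- -m1
  }
  M <- rbind(m1, m2, m3)
  dimnames(M) <- NULL

  out <- structure(list(M = M, model = model, gauge = gauge, cheb = NULL,
                        fit_stats = NULL, rms = NA_real_),
                   class = "projection_model")
  pr <- project(out, points$x, points$y, points$z)
  out$fit_stats <- tibble::tibble(
    point = seq_len(n), u = points$u, v = points$v,
    du = pr$u - points$u, dv = pr$v - points$v)
  out$rms <- sqrt(mean(out$fit_stats$du^2 + out$fit_stats$dv^2))
  out
}

#' @export
print.projection_model <- function(x, ...) {
  cat(sprintf("<projection_model> %s (gauge %s)%s, fit RMS %.4g px on %d points\n",
              x$model, x$gauge,
              if (is.null(x$cheb)) "" else " + Chebyshev-3 refinement",
              x$rms, if (is.null(x$fit_stats)) 0L else nrow(x$fit_stats)))
  invisible(x)
}

# third-degree bivariate Chebyshev basis, total degree <= 3 (10 terms);
# recurrence form so extrapolation beyond [-1,1] stays polynomial
cheb_T <- function(k, x) {
  if (k == 0L) return(rep(1, length(x)))
  if (k == 1L) return(x)
  tm2 <- rep(1, length(x)); tm1 <- x
  for (i in 2:k) { t0 <- 2 * x * tm1 - tm2; tm2 <- tm1; tm1 <- t0 }
  tm1
}

cheb_pairs <- function(deg = 3L) {
  p <- expand.grid(i = 0:deg, j = 0:deg)
  p[p$i + p$j <= deg, , drop = FALSE]
}

cheb_basis <- function(un, vn, deg = 3L) {
  p <- cheb_pairs(deg)
  B <- matrix(0, length(un), nrow(p))
  for (k in seq_len(nrow(p)))
    B[, k] <- cheb_T(p$i[k], un) * cheb_T(p$j[k], vn)
  B
}

cheb_normalize <- function(u, v, box) {
  list(un = if (box$u[2L] > box$u[1L])
              2 * (u - box$u[1L]) / (box$u[2L] - box$u[1L]) - 1 else u * 0,
       vn = if (box$v[2L] > box$v[1L])
              2 * (v - box$v[1L]) / (box$v[2L] - box$v[1L]) - 1 else v * 0)
}

#' Project ground points to hyperspectral pixel coordinates
#'
#' Applies the fitted pushbroom (or projective) mapping, then adds the
#' Chebyshev residual correction if the model carries one.
#'
#' @param model a `projection_model` from [solve_projection()].
#' @param x,y,z ground coordinates (meters), vectors of equal length.
#' @return tibble with real-valued pixel columns `u`, `v`.
#' @export
project <- function(model, x, y, z) {
  stopifnot(inherits(model, "projection_model"))
  X <- rbind(x, y, z, 1)
  M <- model$M
  w <- as.numeric(M[3L, ] %*% X)
  if (any(abs(w) < 1e-12))
    lc_abort("point at (or behind) the camera plane: |w| < 1e-12.",
             "degenerate_error")
  u <- if (model$model == "pushbroom") as.numeric(M[1L, ] %*% X)
       else as.numeric(M[1L, ] %*% X) / w
  v <- as.numeric(M[2L, ] %*% X) / w
  if (!is.null(model$cheb)) {
    nn <- cheb_normalize(u, v, model$cheb$box)
    B <- cheb_basis(nn$un, nn$vn, model$cheb$degree)
    u <- u + as.numeric(B %*% model$cheb$coef_u)
    v <- v + as.numeric(B %*% model$cheb$coef_v)
  }
  tibble::tibble(u = u, v = v)
}

#' Chebyshev residual refinement of a projection model
#'
#' Fits the signed reprojection residuals `(du, dv)` of the fitting points as
#' third-degree bivariate Chebyshev series in `(u, v)` normalized over the
#' fitting-set bounding box, and attaches the correction to the model. A
#' least-squares fit over a basis containing the constant cannot increase the
#' fitting RMS; the smooth series absorbs lens and mounting non-linearities
#' that the linear model cannot express.
#'
#' @param model a fitted `projection_model`.
#' @param points the correspondences to refine against (>= 10, the number of
#'   basis terms).
#' @param degree polynomial total degree (default 3).
#' @return The refined `projection_model` (with `cheb` and updated
#'   `fit_stats`/`rms`).
#' @export
chebyshev_refine <- function(model, points, degree = 3L) {
  stopifnot(inherits(model, "projection_model"))
  points <- tibble::as_tibble(points)
  nterms <- nrow(cheb_pairs(degree))
  if (nrow(points) < nterms)
    lc_abort(sprintf("need >= %d points for a degree-%d bivariate basis, got %d.",
                     nterms, degree, nrow(points)), "degenerate_error")
  base <- model; base$cheb <- NULL
  pr <- project(base, points$x, points$y, points$z)
  du <- points$u - pr$u
  dv <- points$v - pr$v
  box <- list(u = range(pr$u), v = range(pr$v))
  nn <- cheb_normalize(pr$u, pr$v, box)
  B <- cheb_basis(nn$un, nn$vn, degree)
  cu <- qr.solve(qr(B, LAPACK = TRUE), du)
  cv <- qr.solve(qr(B, LAPACK = TRUE), dv)
  out <- model
  out$cheb <- list(degree = degree, box = box, coef_u = as.numeric(cu),
                   coef_v = as.numeric(cv))
  pr2 <- project(out, points$x, points$y, points$z)
  out$fit_stats <- tibble::tibble(
    point = seq_len(nrow(points)), u = points$u, v = points$v,
    du = pr2$u - points$u, dv = pr2$v - points$v)
  rms2 <- sqrt(mean(out$fit_stats$du^2 + out$fit_stats$dv^2))
  if (rms2 > model$rms + 1e-9)
    rlang::warn("Chebyshev refinement did not reduce the fitting RMS.")
  out$rms <- rms2
  out
}

#' Resample point-cloud geometry onto the hyperspectral pixel grid
#'
#' Projects every valid cloud point to hyperspectral pixel coordinates with
#' [project()], then resamples the scattered `(x, y, z)` samples (and any
#' extra per-point layers) to the full image grid by interpolating within
#' each projected cloud grid cell. The hyperspectral image is finer than the
#' depth grid, so each cell covers several pixels; pixels outside the
#' projected support stay invalid.
#'
#' @param model a `projection_model`.
#' @param cloud a [point_cloud()].
#' @param hsi_shape integer `c(rows, cols)` of the target image.
#' @param layers optional named list of extra H x W matrices to carry (e.g.
#'   normal components); interpolated alongside the coordinates.
#' @return A `fused_geometry`: list of rows x cols matrices `x`, `y`, `z`,
#'   `valid`, plus one matrix per extra layer.
#' @export
fuse <- function(model, cloud, hsi_shape, layers = NULL) {
  stopifnot(inherits(model, "projection_model"), inherits(cloud, "point_cloud"))
  hsi_shape <- as.integer(hsi_shape)
  H <- nrow(cloud$z); W <- ncol(cloud$z)
  pv <- cloud$valid
  pr <- project(model, as.numeric(cloud$x[pv]), as.numeric(cloud$y[pv]),
                as.numeric(cloud$z[pv]))
  Up <- matrix(NA_real_, H, W); Vp <- matrix(NA_real_, H, W)
  Up[pv] <- pr$u; Vp[pv] <- pr$v
  inside <- pv & Up > -1 & Up < hsi_shape[1L] & Vp > -1 & Vp < hsi_shape[2L]
  if (!any(inside))
    lc_abort("no cloud point projects inside the image: empty overlap.",
             "empty_error")

  fields <- c(list(x = cloud$x, y = cloud$y, z = cloud$z), layers)

  # enumerate the grid-cell triangles (2 per fully valid quad, 1 per
  # 3-valid-corner quad), then rasterize each: integer pixels inside the
  # projected triangle get barycentric-interpolated field values
  lin <- matrix(seq_len(H * W), H, W)
  a <- lin[-H, -W]; b <- lin[-1L, -W]; cc <- lin[-1L, -1L]; d <- lin[-H, -1L]
  okm <- cbind(inside[as.vector(a)], inside[as.vector(b)],
               inside[as.vector(cc)], inside[as.vector(d)])
  nok <- rowSums(okm)
  full <- nok == 4L
  tris <- rbind(cbind(a[full], b[full], cc[full]),
                cbind(a[full], cc[full], d[full]))
  part <- which(nok == 3L)
  if (length(part)) {
    corners <- cbind(as.vector(a), as.vector(b), as.vector(cc), as.vector(d))
    tri3 <- t(vapply(part, function(q) corners[q, okm[q, ]], integer(3L)))
    tris <- rbind(tris, tri3)
  }
  if (nrow(tris) == 0L)
    lc_abort("projected cloud support covers no whole pixel: empty overlap.",
             "empty_error")

  acc_pix <- vector("list", nrow(tris))
  acc_w <- vector("list", nrow(tris))
  for (t_i in seq_len(nrow(tris))) {
    iv <- tris[t_i, ]
    u0 <- Up[iv]; v0 <- Vp[iv]
    r0 <- max(0, ceiling(min(u0))); r1 <- min(hsi_shape[1L] - 1, floor(max(u0)))
    c0 <- max(0, ceiling(min(v0))); c1 <- min(hsi_shape[2L] - 1, floor(max(v0)))
    if (r1 < r0 || c1 < c0) next
    det <- (v0[2L] - v0[3L]) * (u0[1L] - u0[3L]) +
           (u0[3L] - u0[2L]) * (v0[1L] - v0[3L])
    if (abs(det) < 1e-12) next
    gu <- rep(r0:r1, times = c1 - c0 + 1L)
    gv <- rep(c0:c1, each = r1 - r0 + 1L)
    l1 <- ((v0[2L] - v0[3L]) * (gu - u0[3L]) + (u0[3L] - u0[2L]) * (gv - v0[3L])) / det
    l2 <- ((v0[3L] - v0[1L]) * (gu - u0[3L]) + (u0[1L] - u0[3L]) * (gv - v0[3L])) / det
    l3 <- 1 - l1 - l2
    keep <- l1 >= -1e-9 & l2 >= -1e-9 & l3 >= -1e-9
    if (!any(keep)) next
    acc_pix[[t_i]] <- (gu[keep] + 1L) + gv[keep] * hsi_shape[1L]
    acc_w[[t_i]] <- cbind(l1[keep], l2[keep], l3[keep])
  }
  hit <- !vapply(acc_pix, is.null, logical(1L))
  if (!any(hit))
    lc_abort("projected cloud support covers no whole pixel: empty overlap.",
             "empty_error")
  pix <- unlist(acc_pix[hit], use.names = FALSE)
  Wts <- do.call(rbind, acc_w[hit])
  reps <- vapply(acc_pix[hit], length, integer(1L))
  v1 <- rep(tris[hit, 1L], reps); v2 <- rep(tris[hit, 2L], reps)
  v3 <- rep(tris[hit, 3L], reps)

  out <- lapply(fields, function(f) {
    m <- matrix(NA_real_, hsi_shape[1L], hsi_shape[2L])
    m[pix] <- Wts[, 1L] * f[v1] + Wts[, 2L] * f[v2] + Wts[, 3L] * f[v3]
    m
  })
  filled <- matrix(FALSE, hsi_shape[1L], hsi_shape[2L])
  filled[pix] <- TRUE
  structure(c(out, list(valid = filled)), class = "fused_geometry")
}

#' Transport cloud-derived leaf angles to the hyperspectral grid
#'
#' Estimates surface normals on the raw metric cloud (avoiding
#' differentiation of resampled data), carries the normal components through
#' [fuse()], renormalizes per pixel, and converts to tilt angle/orientation.
#'
#' @inheritParams fuse
#' @param window normal-estimation window, see [estimate_normals()].
#' @param theta_min orientation cutoff, see [angle_map()].
#' @return An [angle_map()] at the hyperspectral image resolution.
#' @export
fuse_angles <- function(model, cloud, hsi_shape, window = 5L, theta_min = 2) {
  nf <- estimate_normals(cloud, window = window)
  cl2 <- cloud
  cl2$valid <- cloud$valid & nf$valid
  fg <- fuse(model, cl2, hsi_shape,
             layers = list(nu = nf$u, nv = nf$v, nw = nf$w))
  nrm <- sqrt(fg$nu^2 + fg$nv^2 + fg$nw^2)
  ok <- fg$valid & is.finite(nrm) & nrm > 1e-6
  u <- fg$nu / nrm; v <- fg$nv / nrm; w <- fg$nw / nrm
  u[!ok] <- NA_real_; v[!ok] <- NA_real_; w[!ok] <- NA_real_
  nf2 <- structure(list(u = u, v = v, w = w, valid = ok),
                   class = "normal_field")
  angle_map(nf2, theta_min = theta_min)
}

#' Physical pixel resolution
#'
#' @param image_extent_px image extent in pixels (> 0).
#' @param physical_extent_mm physical extent in millimeters (> 0).
#' @return resolution in mm/pixel.
#' @examples
#' pixel_resolution(1886, 200) # 0.1060
#' pixel_resolution(782, 200)  # 0.2558
#' @export
pixel_resolution <- function(image_extent_px, physical_extent_mm) {
  if (!is_scalar_number(image_extent_px) || image_extent_px <= 0 ||
      !is_scalar_number(physical_extent_mm) || physical_extent_mm <= 0)
    lc_abort("extents must be positive numbers.", "value_error")
  physical_extent_mm / image_extent_px
}

#' Write / read a projection model as JSON
#'
#' Stores `M` row-major with the model form, gauge tag and any Chebyshev
#' coefficients with their normalization box.
#'
#' @param model a `projection_model`.
#' @param path JSON path.
#' @export
write_projection <- function(model, path) {
  stopifnot(inherits(model, "projection_model"))
  jsonlite::write_json(
    list(M = as.numeric(t(model$M)), model = model$model, gauge = model$gauge,
         rms = model$rms,
         cheb = if (is.null(model$cheb)) NULL else list(
           degree = model$cheb$degree, box_u = model$cheb$box$u,
           box_v = model$cheb$box$v, coef_u = model$cheb$coef_u,
           coef_v = model$cheb$coef_v)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_projection
#' @export
read_projection <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cheb <- NULL
  if (!is.null(j$cheb) && length(j$cheb))
    cheb <- list(degree = j$cheb$degree,
                 box = list(u = j$cheb$box_u, v = j$cheb$box_v),
                 coef_u = j$cheb$coef_u, coef_v = j$cheb$coef_v)
  structure(list(M = matrix(j$M, 3L, 4L, byrow = TRUE), model = j$model,
                 gauge = j$gauge, cheb = cheb, fit_stats = NULL,
                 rms = j$rms %||% NA_real_),
            class = "projection_model")
}

#' Corner mismatch summary
#'
#' Residual bookkeeping between detected and model-estimated corner pixel
#' coordinates: the maximum absolute row and column mismatches, optionally in
#' millimeters given the pixel resolutions.
#'
#' @param corners data frame with columns `u_obs, v_obs, u_est, v_est`
#'   (pixels).
#' @param res_row_mm,res_col_mm optional mm/pixel resolutions.
#' @return tibble with `max_row_px`, `max_col_px` (and `max_row_mm`,
#'   `max_col_mm` when resolutions are given).
#' @export
corner_mismatch <- function(corners, res_row_mm = NULL, res_col_mm = NULL) {
  need <- c("u_obs", "v_obs", "u_est", "v_est")
  if (!all(need %in% names(corners)))
    lc_abort("corner table needs columns u_obs,v_obs,u_est,v_est.",
             "dimension_error")
  out <- tibble::tibble(
    max_row_px = max(abs(corners$u_obs - corners$u_est)),
    max_col_px = max(abs(corners$v_obs - corners$v_est)))
  if (!is.null(res_row_mm)) out$max_row_mm <- out$max_row_px * res_row_mm
  if (!is.null(res_col_mm)) out$max_col_mm <- out$max_col_px * res_col_mm
  out
}
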