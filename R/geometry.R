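#' Organized point cloud
#'
#' An H x W grid of 3D points in a right-handed metric frame (meters) with z
#' the vertical axis, as produced by a depth camera after deprojection.
#' Invalid points (dropouts) are carried in `valid`; non-finite coordinates
#' are invalid automatically.
#'
#' @param x,y,z H x W numeric matrices (meters).
#' @param valid optional H x W logical matrix; intersected with finiteness.
#' @param color optional H x W x 3 array.
#' @return An object of class `point_cloud`.
#' @export
point_cloud <- function(x, y, z, valid = NULL, color = NULL) {
  if (!is.matrix(x) || !identical(dim(x), dim(y)) || !identical(dim(x), dim(z)))
    lc_abort("x, y, z must be H x W matrices of identical shape.",
             "dimension_error")
  fin <- is.finite(x) & is.finite(y) & is.finite(z)
  if (!is.null(valid)) {
    if (!identical(dim(valid), dim(x)))
      lc_abort("`valid` shape does not match the grid.", "dimension_error")
    fin <- fin & valid
  }
  structure(list(x = x, y = y, z = z, valid = fin, color = color),
            class = "point_cloud")
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d x %d grid, %d valid points\n",
              nrow(x$z), ncol(x$z), sum(x$valid)))
  invisible(x)
}

#' Per-pixel surface normals by local plane fitting
#'
#' For every grid point, a plane is fit by least squares to the valid points
#' of the surrounding `window` x `window` neighborhood (the local surface
#' patch); the unit normal is the eigenvector of the smallest eigenvalue of
#' the local covariance, sign-flipped so its vertical component is >= 0.
#' Pixels with fewer than 3 valid neighbors, or with collinear support, are
#' invalid.
#'
#' @param cloud a [point_cloud()].
#' @param window odd integer window size >= 3 (default 5).
#' @return A `normal_field`: list of H x W matrices `u`, `v`, `w` (the normal
#'   components) and `valid`.
#' @export
estimate_normals <- function(cloud, window = 5L) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (window < 3L || window %% 2L == 0L)
    lc_abort("`window` must be an odd integer >= 3.", "parameter_error")
  r <- (window - 1L) %/% 2L
  m <- cloud$valid
  X <- ifelse(m, cloud$x, 0); Y <- ifelse(m, cloud$y, 0)
  Z <- ifelse(m, cloud$z, 0)
  n <- boxsum2d(m * 1, r)
  Sx <- boxsum2d(X, r); Sy <- boxsum2d(Y, r); Sz <- boxsum2d(Z, r)
  Sxx <- boxsum2d(X * X, r); Syy <- boxsum2d(Y * Y, r); Szz <- boxsum2d(Z * Z, r)
  Sxy <- boxsum2d(X * Y, r); Sxz <- boxsum2d(X * Z, r); Syz <- boxsum2d(Y * Z, r)

  H <- nrow(m); W <- ncol(m)
  U <- Vc <- Wc <- matrix(NA_real_, H, W)
  ok <- m & n >= 3
  idx <- which(ok)
  for (p in idx) {
    np <- n[p]
    mx <- Sx[p] / np; my <- Sy[p] / np; mz <- Sz[p] / np
    C <- matrix(c(Sxx[p] / np - mx * mx, Sxy[p] / np - mx * my, Sxz[p] / np - mx * mz,
                  Sxy[p] / np - mx * my, Syy[p] / np - my * my, Syz[p] / np - my * mz,
                  Sxz[p] / np - mx * mz, Syz[p] / np - my * mz, Szz[p] / np - mz * mz),
                3L, 3L)
    e <- eigen(C, symmetric = TRUE)
    # collinear support: the two largest eigenvalues must both carry extent
    if (e$values[2L] <= max(e$values[1L] * 1e-12, 1e-20)) next
    v <- e$vectors[, 3L]
    if (v[3L] < 0) v <- -v
    U[p] <- v[1L]; Vc[p] <- v[2L]; Wc[p] <- v[3L]
  }
  structure(list(u = U, v = Vc, w = Wc,
                 valid = is.finite(U) & is.finite(Vc) & is.finite(Wc)),
            class = "normal_field")
}

#' Convert a unit surface normal to tilt orientation and tilt angle
#'
#' With normal `n = (u, v, w)` (w >= 0 upward), the normal's elevation above
#' the horizontal plane is `beta = atan2(w, sqrt(u^2 + v^2))` in degrees; a
#' horizontal surface has `beta = 90`. The tilt angle reported is measured
#' from the horizontal, `theta = 90 - beta`, matching a rotation platform
#' where 0 degrees means flat. The tilt orientation is
#' `alpha = atan2(v, u)` folded to `[0, 360)` (the fold realizes the quadrant
#' offset exactly); `alpha` is undefined (`NA`) when `theta < theta_min`
#' because a near-horizontal surface has no meaningful azimuth.
#'
#' @param n numeric length-3 unit vector (tolerance 1e-6 on the norm).
#' @param theta_min tilt (degrees) below which orientation is undefined.
#' @return list with `alpha` (deg in `[0,360)` or `NA`), `theta` (deg in
#'   `[0,90]`) and `beta` (deg).
#' @examples
#' normal_to_angles(c(sin(pi / 6), 0, cos(pi / 6)))$theta # 30
#' @export
normal_to_angles <- function(n, theta_min = 2) {
  if (length(n) != 3L || !all(is.finite(n)))
    lc_abort("normal must be a finite length-3 vector.", "value_error")
  nn <- sqrt(sum(n^2))
  if (nn < 1e-12)
    lc_abort("zero normal vector.", "value_error")
  if (abs(nn - 1) > 1e-6)
    lc_abort(sprintf("normal is not unit length (|n| = %.8f).", nn),
             "value_error")
  if (n[3L] < 0) n <- -n
  beta <- rad2deg(atan2(n[3L], sqrt(n[1L]^2 + n[2L]^2)))
  theta <- 90 - beta
  alpha <- if (theta < theta_min) NA_real_ else rad2deg(atan2(n[2L], n[1L])) %% 360
  if (!is.na(alpha) && alpha >= 360 - 1e-9) alpha <- 0
  list(alpha = alpha, theta = theta, beta = beta)
}

#' Per-pixel tilt angle and orientation map
#'
#' Elementwise [normal_to_angles()] over a normal field.
#'
#' @param normals a `normal_field` from [estimate_normals()].
#' @param theta_min tilt (deg) below which orientation is undefined (default 2).
#' @return An `angle_map`: list of H x W matrices `theta` (deg from
#'   horizontal, `[0, 90]`), `alpha` (deg, `[0, 360)`, `NA` where undefined or
#'   invalid) and `valid`.
#' @export
angle_map <- function(normals, theta_min = 2) {
  stopifnot(inherits(normals, "normal_field"))
  u <- normals$u; v <- normals$v; w <- normals$w
  beta <- rad2deg(atan2(w, sqrt(u^2 + v^2)))
  theta <- 90 - beta
  alpha <- rad2deg(atan2(v, u)) %% 360
  alpha[!is.na(alpha) & alpha >= 360 - 1e-9] <- 0
  alpha[!is.na(theta) & theta < theta_min] <- NA_real_
  theta[!normals$valid] <- NA_real_
  alpha[!normals$valid] <- NA_real_
  structure(list(theta = theta, alpha = alpha, valid = normals$valid),
            class = "angle_map")
}

#' @export
print.angle_map <- function(x, ...) {
  ok <- x$valid
  cat(sprintf("<angle_map> %d x %d, %d valid; median tilt %.1f deg\n",
              nrow(x$theta), ncol(x$theta), sum(ok),
              stats::median(x$theta[ok])))
  invisible(x)
}

#' Write / read an angle map as two-band float32 binary + JSON sidecar
#'
#' Band 1 is tilt `theta`, band 2 orientation `alpha` (NaN = invalid).
#'
#' @param angles an [angle_map()].
#' @param stem output stem; writes `<stem>.bin` and `<stem>.json`.
#' @export
write_angle_map <- function(angles, stem) {
  stopifnot(inherits(angles, "angle_map"))
  pack <- function(m) { v <- as.numeric(t(m)); v[is.na(v)] <- NaN; v }
  con <- file(paste0(stem, ".bin"), "wb")
  writeBin(c(pack(angles$theta), pack(angles$alpha)), con, size = 4L,
           endian = "little"); close(con)
  jsonlite::write_json(
    list(rows = nrow(angles$theta), cols = ncol(angles$theta),
         bands = c("theta_deg", "alpha_deg"), dtype = "float32",
         order = "row-major", invalid = "NaN"),
    paste0(stem, ".json"), auto_unbox = TRUE)
  invisible(stem)
}

#' @rdname write_angle_map
#' @export
read_angle_map <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  n <- meta$rows * meta$cols
  con <- file(paste0(stem, ".bin"), "rb"); on.exit(close(con))
  v <- readBin(con, numeric(), n = 2L * n, size = 4L, endian = "little")
  unpack <- function(k) {
    m <- t(matrix(v[((k - 1L) * n + 1L):(k * n)], meta$cols, meta$rows))
    m[is.nan(m)] <- NA_real_; m
  }
  theta <- unpack(1L); alpha <- unpack(2L)
  structure(list(theta = theta, alpha = alpha, valid = !is.na(theta)),
            class = "angle_map")
}
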