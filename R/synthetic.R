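#' Species angular-response profile
#'
#' Bundles the baseline leaf reflectance spectrum (on the generator's 5-band
#' axis) with the parameters of the angular NDVI response used by
#' [true_ratio()]. The built-in profiles encode the observed species
#' behavior: soybean NDVI rises slightly to a peak near 30 degrees and then
#' falls well below the horizontal-leaf value by 80 degrees, while corn peaks
#' near 50 degrees and stays above the horizontal value at 80 degrees.
#'
#' @param name `"soybean"` or `"corn"` for the built-in parameter sets, or
#'   any label when all parameters are supplied.
#' @param peak tilt angle (deg) of maximum ratio.
#' @param rise_amp amplitude of the sine rise term.
#' @param fall_amp amplitude of the quadratic post-peak fall term.
#' @param orient_mod orientation modulation amplitude (relative).
#' @param orient_phase orientation (deg) of maximum modulation.
#' @param texture_sd spatial NDVI texture (veins etc.) std. dev. for scenes.
#' @return An object of class `species_profile`.
#' @export
species_profile <- function(name = c("soybean", "corn"), peak = NULL,
                            rise_amp = NULL, fall_amp = NULL,
                            orient_mod = 0.03, orient_phase = 0,
                            texture_sd = 0.02) {
  name <- if (length(name) == 1L) name else match.arg(name)
  defaults <- list(
    soybean = list(peak = 30, rise_amp = 0.10, fall_amp = 0.20),
    corn = list(peak = 50, rise_amp = 0.15, fall_amp = 0.05))
  if (name %in% names(defaults)) {
    d <- defaults[[name]]
    peak <- peak %||% d$peak
    rise_amp <- rise_amp %||% d$rise_amp
    fall_amp <- fall_amp %||% d$fall_amp
  }
  if (is.null(peak) || is.null(rise_amp) || is.null(fall_amp))
    lc_abort("peak, rise_amp and fall_amp are required for custom profiles.",
             "parameter_error")
  bands <- c(560, 680, 732, 800, 900)
  spectrum <- c(0.10, 0.05, 0.35, 0.55, 0.52)
  structure(list(name = name, bands = bands, spectrum = spectrum,
                 background = rep(0.25, 5L),
                 ndvi0 = (spectrum[4L] - spectrum[2L]) /
                         (spectrum[4L] + spectrum[2L]),
                 peak = peak, rise_amp = rise_amp, fall_amp = fall_amp,
                 orient_mod = orient_mod, orient_phase = orient_phase,
                 texture_sd = texture_sd),
            class = "species_profile")
}

#' True angular NDVI-ratio response of a synthetic species
#'
#' The generator's ground-truth ratio of NDVI at pose `(theta, alpha)` to the
#' horizontal-leaf NDVI: a smooth rise-then-fall curve
#' `r = 1 + (A sin(pi theta / (2 peak)) - B max(0, (theta - peak) /
#' (80 - peak))^2) (1 + m cos(alpha - alpha0))`,
#' anchored at `r(0, alpha) = 1`. The sine term peaks exactly at `peak`; the
#' quadratic term starts with zero slope there, so the maximum stays at the
#' species' peak angle while the amplitudes of rise and fall stay
#' independent.
#'
#' @param profile a [species_profile()].
#' @param theta tilt angle(s), degrees, in `[0, 90]`.
#' @param alpha orientation(s), degrees.
#' @return numeric ratio(s).
#' @examples
#' sp <- species_profile("soybean")
#' true_ratio(sp, 0, 120) # exactly 1
#' @export
true_ratio <- function(profile, theta, alpha) {
  stopifnot(inherits(profile, "species_profile"))
  dev <- profile$rise_amp * sin(pi * theta / (2 * profile$peak)) -
    profile$fall_amp * (pmax(0, theta - profile$peak) / (80 - profile$peak))^2
  1 + dev * (1 + profile$orient_mod *
               cos(deg2rad(alpha - profile$orient_phase)))
}

#' Synthetic pushbroom camera
#'
#' A linear pushbroom projection in the package's convention: the scan-axis
#' row is affine in the ground x coordinate, `u = x / ru + u0`; the column is
#' perspective within the scan line from a camera at height `zc`,
#' `v = (y zc / rv + v0 (zc - z)) / (zc - z)`, so `dv/dy = 1/rv` at the table
#' plane `z = 0`.
#'
#' @param ru,rv row/column resolution (meters per pixel at z = 0).
#' @param zc camera height above the table (m), default 0.63.
#' @param u0,v0 pixel offsets of the world origin.
#' @return A `projection_model`.
#' @export
synthetic_camera <- function(ru = 1.06e-4, rv = 2.558e-4, zc = 0.63,
                             u0 = 0, v0 = 0) {
  f <- zc / rv
  M <- rbind(c(1 / ru, 0, 0, u0),
             c(0, f, -v0, v0 * zc),
             c(0, 0, -1, zc))
  structure(list(M = M, model = "pushbroom", gauge = "norm_m3_spatial",
                 cheb = NULL, fit_stats = NULL, rms = 0),
            class = "projection_model")
}

# smooth random field: a few random sinusoids over the scene, scaled to a
# target standard deviation; deterministic under the caller's RNG state
smooth_field <- function(x, y, sd_target, n_waves = 4L, wavelength_m = 0.012) {
  if (sd_target <= 0) return(x * 0)
  f <- matrix(0, nrow(x), ncol(x))
  for (k in seq_len(n_waves)) {
    fr <- 2 * pi / (wavelength_m * stats::runif(1L, 0.6, 1.8))
    th <- stats::runif(1L, 0, 2 * pi)
    ph <- stats::runif(1L, 0, 2 * pi)
    f <- f + sin(fr * (x * cos(th) + y * sin(th)) + ph)
  }
  s <- stats::sd(as.numeric(f))
  if (s < 1e-12) return(x * 0)
  f * (sd_target / s)
}

leaf_surface <- function(geometry) {
  # returns list(z_fun(x, y), inside(x, y), theta(x, y), alpha(x, y))
  type <- geometry$type %||% "plane"
  if (type == "plane") {
    theta <- geometry$theta; alpha <- geometry$alpha %||% 0
    side <- (geometry$side_mm %||% 40) / 1000
    g <- -tan(deg2rad(theta)) * c(cos(deg2rad(alpha)), sin(deg2rad(alpha)))
    list(
      z = function(x, y) g[1L] * x + g[2L] * y, # plane through the origin
      inside = function(x, y) {
        t_ax <- x * cos(deg2rad(alpha)) + y * sin(deg2rad(alpha))
        p_ax <- -x * sin(deg2rad(alpha)) + y * cos(deg2rad(alpha))
        abs(t_ax) <= side / 2 * cos(deg2rad(theta)) + 1e-12 &
          abs(p_ax) <= side / 2 + 1e-12
      },
      theta = function(x, y) x * 0 + theta,
      alpha = function(x, y) {
        if (theta < 1e-9) x * NA_real_ else x * 0 + (alpha %% 360)
      })
  } else if (type == "arch") {
    h <- (geometry$height_mm %||% 12) / 1000
    w <- (geometry$width_mm %||% 40) / 1000
    len <- (geometry$length_mm %||% 120) / 1000
    list(
      z = function(x, y) ifelse(abs(x) <= w / 2, h * cos(pi * x / w), 0),
      inside = function(x, y) abs(x) <= w / 2 & abs(y) <= len / 2,
      theta = function(x, y) {
        slope <- -h * pi / w * sin(pi * x / w)
        rad2deg(atan(abs(slope)))
      },
      alpha = function(x, y) {
        slope <- -h * pi / w * sin(pi * x / w)
        a <- ifelse(slope < 0, 0, 180)
        a[abs(slope) < tan(deg2rad(1e-6))] <- NA_real_
        a
      })
  } else lc_abort(sprintf("unknown leaf geometry '%s'.", type),
                  "parameter_error")
}

#' Synthetic leaf scene: hyperspectral cube, point cloud and ground truth
#'
#' Renders a leaf of known geometry through a synthetic pushbroom camera.
#' The leaf's flat-reference NDVI field (baseline plus smooth vein-like
#' texture) is transformed per pixel by the species' [true_ratio()] at the
#' local `(theta, alpha)`, band reflectances are synthesized to realize that
#' NDVI, and multiplicative log-normal sensor noise plus a smooth
#' per-acquisition drift field are applied. The organized point cloud samples
#' the same surface on a metric grid (the depth camera is coarser than the
#' hyperspectral image) with optional additive depth noise.
#'
#' @param profile a [species_profile()].
#' @param geometry `list(type = "plane", theta =, alpha =, side_mm = 40)` or
#'   `list(type = "arch", height_mm = 12, width_mm = 40, length_mm = 120)`.
#' @param shape_px hyperspectral `c(rows, cols)` (default `c(160, 120)`).
#' @param sigma multiplicative sensor noise (log-sd, default 0.01).
#' @param acq_sigma per-acquisition smooth NDVI drift (sd, default 0.005).
#' @param texture logical; include the flat-NDVI texture field.
#' @param cloud_pitch_mm depth grid pitch (default 1 mm).
#' @param sigma_z additive depth noise sd (meters, default 0).
#' @param camera optional `projection_model`; default centers a
#'   0.35 mm/px camera on the scene.
#' @param seed RNG seed (restores global RNG state).
#' @param texture_seed optional separate seed for the leaf's intrinsic
#'   flat-NDVI texture: scenes of the same physical leaf in different poses
#'   share `texture_seed` while `seed` varies the acquisition (noise, drift).
#' @return list with `cube` (reflectance [hsi_cube()]), `cloud`
#'   ([point_cloud()]), `correspondences` (16 exact two-height fiducials) and
#'   `truth` (per-HSI-pixel `theta`, `alpha`, `flat_ndvi`, `ratio`, `leaf`
#'   mask; per-cloud-pixel `cloud_theta`, `cloud_alpha`, `cloud_leaf`;
#'   the camera `model`).
#' @export
make_leaf_scene <- function(profile, geometry = list(type = "plane",
                                                     theta = 30, alpha = 0),
                            shape_px = c(160L, 120L), sigma = 0.01,
                            acq_sigma = 0.005, texture = TRUE,
                            cloud_pitch_mm = 1, sigma_z = 0, camera = NULL,
                            seed = NULL, texture_seed = NULL) {
  stopifnot(inherits(profile, "species_profile"))
  with_seed(seed, {
    rows <- as.integer(shape_px[1L]); cols <- as.integer(shape_px[2L])
    ru <- 3.5e-4; rv <- 3.5e-4; zc <- 0.63
    camera <- camera %||% synthetic_camera(ru, rv, zc,
                                           u0 = (rows - 1) / 2,
                                           v0 = (cols - 1) / 2)
    M <- camera$M
    surf <- leaf_surface(geometry)

    # invert the camera per pixel: u gives x directly (scan axis); the
    # column is solved by fixed-point iteration on the surface height
    ug <- matrix(rep(0:(rows - 1L), cols), rows, cols)
    vg <- matrix(rep(0:(cols - 1L), each = rows), rows, cols)
    x <- (ug - M[1L, 4L]) / M[1L, 1L]
    fcol <- M[2L, 2L]; v0 <- (camera$M[2L, 3L] * -1)
    z <- x * 0
    for (it in 1:3) {
      y <- (vg - v0) * (zc - z) / fcol
      inl <- surf$inside(x, y)
      z <- ifelse(inl, surf$z(x, y), 0)
    }
    leaf <- surf$inside(x, y)
    theta_t <- ifelse(leaf, surf$theta(x, y), NA_real_)
    alpha_t <- matrix(NA_real_, rows, cols)
    alpha_t[leaf] <- surf$alpha(x, y)[leaf]

    flat <- matrix(profile$ndvi0, rows, cols)
    if (texture && profile$texture_sd > 0) {
      tex <- if (is.null(texture_seed))
        smooth_field(x, y, profile$texture_sd)
      else with_seed(texture_seed, smooth_field(x, y, profile$texture_sd))
      flat <- flat + tex
    }
    ratio_t <- matrix(1, rows, cols)
    al_eff <- ifelse(is.na(alpha_t), 0, alpha_t) # marginal pose for flat pixels
    ratio_t[leaf] <- true_ratio(profile, theta_t[leaf], al_eff[leaf])
    drift <- if (acq_sigma > 0) smooth_field(x, y, acq_sigma) else x * 0
    ndvi_px <- pmin(0.999, pmax(-0.999, flat * ratio_t * exp(drift)))

    # synthesize band reflectances: RED/NIR realize the pixel NDVI holding
    # their sum at the baseline leaf level; other bands keep the spectrum
    S <- profile$spectrum[2L] + profile$spectrum[4L]
    cube_a <- array(0, c(rows, cols, 5L))
    for (b in 1:5) cube_a[, , b] <- profile$background[b]
    red <- S * (1 - ndvi_px) / 2
    nir <- S * (1 + ndvi_px) / 2
    planes <- list(profile$spectrum[1L] + x * 0, red,
                   profile$spectrum[3L] + x * 0, nir,
                   profile$spectrum[5L] + x * 0)
    for (b in 1:5) {
      p <- cube_a[, , b]
      p[leaf] <- planes[[b]][leaf]
      cube_a[, , b] <- p
    }
    if (sigma > 0)
      cube_a <- cube_a * exp(array(stats::rnorm(length(cube_a), 0, sigma),
                                   dim(cube_a)))
    cube <- hsi_cube(cube_a, profile$bands, kind = "reflectance")

    # organized metric cloud over the scene footprint
    pitch <- cloud_pitch_mm / 1000
    xr <- range(x); yr <- range(y)
    cx <- seq(xr[1L], xr[2L], by = pitch)
    cy <- seq(yr[1L], yr[2L], by = pitch)
    CX <- matrix(rep(cx, length(cy)), length(cx), length(cy))
    CY <- matrix(rep(cy, each = length(cx)), length(cx), length(cy))
    cin <- surf$inside(CX, CY)
    CZ <- ifelse(cin, surf$z(CX, CY), 0)
    if (sigma_z > 0)
      CZ <- CZ + matrix(stats::rnorm(length(CZ), 0, sigma_z), nrow(CZ))
    cloud <- point_cloud(CX, CY, CZ)
    cloud_theta <- ifelse(cin, surf$theta(CX, CY), 0)
    cloud_alpha <- matrix(NA_real_, nrow(CX), ncol(CX))
    cloud_alpha[cin] <- surf$alpha(CX, CY)[cin]

    # two-height fiducial frame for projection fitting
    ext <- max(abs(c(xr, yr))) * 0.95
    fid <- expand.grid(x = c(-ext, 0, ext), y = c(-ext, 0, ext))
    fid <- fid[!(fid$x == 0 & fid$y == 0), ]
    fid <- rbind(cbind(fid, z = 0), cbind(fid, z = 0.02))
    pr <- project(camera, fid$x, fid$y, fid$z)
    corr <- tibble::tibble(u = pr$u, v = pr$v, x = fid$x, y = fid$y,
                           z = fid$z)

    list(cube = cube, cloud = cloud, correspondences = corr,
         truth = list(theta = theta_t, alpha = alpha_t, flat_ndvi = flat,
                      ratio = ratio_t, leaf = leaf, ndvi = ndvi_px,
                      cloud_theta = cloud_theta, cloud_alpha = cloud_alpha,
                      cloud_leaf = cin, model = camera))
  })
}

#' Synthetic two-layer checkerboard calibration scene
#'
#' A 200 x 200 mm checkerboard with a raised central layer (default 50 mm
#' height difference), imaged by a [synthetic_camera()]: returns a small
#' rendered cube, an organized point cloud of the platform, and 13 exact (or
#' pixel-quantized) corner correspondences spanning both layers.
#'
#' @param square_mm checker square size (default 25).
#' @param board_mm board extent (default 200).
#' @param layer_gap_mm height difference between layers (default 50).
#' @param camera optional `projection_model`; default uses the hyperspectral
#'   system's nominal 0.106 / 0.2558 mm/px resolutions.
#' @param noise `"none"` for exact correspondences or `"quantize"` to round
#'   pixel coordinates to integers (corner-detection quantization).
#' @param sigma_z additive depth noise on correspondence z (meters).
#' @param seed RNG seed.
#' @return list with `cube`, `cloud`, `correspondences`, `truth`
#'   (`model`, `layer_gap_mm`).
#' @export
make_checkerboard_scene <- function(square_mm = 25, board_mm = 200,
                                    layer_gap_mm = 50, camera = NULL,
                                    noise = c("none", "quantize"),
                                    sigma_z = 0, seed = NULL) {
  noise <- match.arg(noise)
  if (layer_gap_mm <= 0)
    lc_abort("need two distinct height layers (layer_gap_mm > 0).",
             "parameter_error")
  with_seed(seed, {
    camera <- camera %||% synthetic_camera(u0 = 50, v0 = 30)
    b <- board_mm / 1000; s <- square_mm / 1000; gap <- layer_gap_mm / 1000
    top0 <- b / 4; top1 <- 3 * b / 4 # raised central quarter
    zlev <- function(x, y) ifelse(x >= top0 & x <= top1 & y >= top0 &
                                    y <= top1, gap, 0)
    # 8 bottom-layer and 5 top-layer corners (all on checker intersections)
    pts <- rbind(
      cbind(x = c(1, 1, 1, 4, 7, 7, 7, 4) * s, y = c(1, 4, 7, 7, 7, 4, 1, 1) * s),
      cbind(x = c(3, 3, 5, 5, 4) * s, y = c(3, 5, 5, 3, 4) * s))
    z <- zlev(pts[, 1L], pts[, 2L])
    pr <- project(camera, pts[, 1L], pts[, 2L], z)
    u <- pr$u; v <- pr$v
    if (noise == "quantize") { u <- round(u); v <- round(v) }
    if (sigma_z > 0) z <- z + stats::rnorm(length(z), 0, sigma_z)
    corr <- tibble::tibble(u = u, v = v, x = pts[, 1L], y = pts[, 2L], z = z)

    # organized cloud of the platform (2 mm pitch) and a small rendered cube
    g <- seq(0, b, by = 0.002)
    CX <- matrix(rep(g, length(g)), length(g), length(g))
    CY <- matrix(rep(g, each = length(g)), length(g), length(g))
    cloud <- point_cloud(CX, CY, zlev(CX, CY))

    n_px <- 120L
    gx <- seq(0, b, length.out = n_px)
    PX <- matrix(rep(gx, n_px), n_px, n_px)
    PY <- matrix(rep(gx, each = n_px), n_px, n_px)
    white <- (floor(PX / s) + floor(PY / s)) %% 2 == 0
    refl <- ifelse(white, 0.9, 0.05)
    bands <- c(560, 680, 732, 800, 900)
    cube <- hsi_cube(array(rep(refl, 5L), c(n_px, n_px, 5L)), bands,
                     kind = "reflectance")
    list(cube = cube, cloud = cloud, correspondences = corr,
         truth = list(model = camera, layer_gap_mm = layer_gap_mm))
  })
}

#' Simulate the rotation-protocol experiment
#'
#' Generates the full pose grid of the imaging protocol — 8 tilt orientations
#' (0 to 315 deg, step 45) times 9 tilt angles (0 to 80 deg, step 10), i.e.
#' 72 poses per leaf — with a leaf-level random baseline NDVI and
#' multiplicative measurement noise around the species' [true_ratio()]
#' response.
#'
#' @param profile a [species_profile()].
#' @param n_leaves number of leaf pieces (8 reproduces the soybean design's
#'   576 scans, 24 the corn design's 1728).
#' @param sigma multiplicative noise on mean NDVI (log-sd, default 0.01).
#' @param baseline_sd leaf-to-leaf baseline NDVI sd (default 0.02).
#' @param seed RNG seed.
#' @return tibble of rotation records
#'   (`leaf_id, species, orientation_deg, angle_deg, mean_ndvi`).
#' @export
simulate_rotation_experiment <- function(profile, n_leaves, sigma = 0.01,
                                         baseline_sd = 0.02, seed = NULL) {
  stopifnot(inherits(profile, "species_profile"))
  if (n_leaves < 1L) lc_abort("`n_leaves` must be >= 1.", "parameter_error")
  with_seed(seed, {
    grid <- expand.grid(angle_deg = seq(0, 80, 10),
                        orientation_deg = seq(0, 315, 45))
    out <- lapply(seq_len(n_leaves), function(i) {
      base <- stats::rnorm(1L, profile$ndvi0, baseline_sd)
      r <- true_ratio(profile, grid$angle_deg, grid$orientation_deg)
      tibble::tibble(
        leaf_id = sprintf("%s_%02d", profile$name, i),
        species = profile$name,
        orientation_deg = grid$orientation_deg,
        angle_deg = grid$angle_deg,
        mean_ndvi = base * r * exp(stats::rnorm(nrow(grid), 0, sigma)))
    })
    dplyr::arrange(dplyr::bind_rows(out), .data$leaf_id,
                   .data$orientation_deg, .data$angle_deg)
  })
}
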