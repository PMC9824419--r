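#' Pipeline configuration
#'
#' Flat configuration record for the calibration pipeline. Values are plain
#' scalars/vectors so the whole record round-trips losslessly through the
#' `key = value` config-file format of [write_config()] / [read_config()].
#'
#' @param red,nir NDVI wavelengths (nm).
#' @param red_edge segmentation wavelength pair (nm).
#' @param seg_threshold red-edge index threshold or `"auto"`.
#' @param window normal-estimation window (odd, pixels).
#' @param theta_min tilt below which orientation is undefined (deg).
#' @param svr_cost,svr_epsilon,svr_gamma,svr_folds SVR hyperparameters.
#' @param ratio_floor smallest ratio accepted by [apply_3d_calibration()].
#' @param reference ratio-table reference convention.
#' @param seed integer seed for stochastic steps.
#' @return named list of class `leafcal_config`.
#' @export
leafcal_config <- function(red = 680, nir = 800, red_edge = c(680, 732),
                           seg_threshold = "auto", window = 5L, theta_min = 2,
                           svr_cost = 10, svr_epsilon = 0.01,
                           svr_gamma = "scale", svr_folds = 5L,
                           ratio_floor = 0.1,
                           reference = "per-orientation", seed = 1L) {
  structure(list(red = red, nir = nir, red_edge = red_edge,
                 seg_threshold = seg_threshold, window = window,
                 theta_min = theta_min, svr_cost = svr_cost,
                 svr_epsilon = svr_epsilon, svr_gamma = svr_gamma,
                 svr_folds = svr_folds, ratio_floor = ratio_floor,
                 reference = reference, seed = seed),
            class = "leafcal_config")
}

#' Write / read a flat `key = value` configuration file
#'
#' Numeric vectors are comma-separated; strings are kept verbatim. Reading
#' re-types each value against the [leafcal_config()] defaults so the record
#' round-trips losslessly.
#'
#' @param config a [leafcal_config()].
#' @param path file path.
#' @export
write_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    sprintf("%s = %s", k, paste(config[[k]], collapse = ","))
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "\\s*=\\s*")
  cfg <- leafcal_config()
  for (p in kv) {
    k <- trimws(p[1L]); val <- strsplit(trimws(p[2L]), ",")[[1L]]
    if (!k %in% names(cfg)) next
    proto <- cfg[[k]]
    cfg[[k]] <- if (is.numeric(proto) && !anyNA(suppressWarnings(as.numeric(val))))
      as.numeric(val) else val
    # mixed-type fields (threshold/gamma may be "auto"/"scale" or a number)
    if (k %in% c("seg_threshold", "svr_gamma") &&
        !anyNA(suppressWarnings(as.numeric(val))))
      cfg[[k]] <- as.numeric(val)
    if (k %in% c("window", "svr_folds", "seed")) cfg[[k]] <- as.integer(cfg[[k]])
  }
  cfg
}

#' Run one calibration protocol on a leaf scene
#'
#' The three protocols compared by the pipeline:
#' * `ideal` — a flat leaf calibrated by the flat white reference: NDVI is
#'   computed directly (the standard).
#' * `practical` — a curved/tilted leaf calibrated by the flat white
#'   reference: the same NDVI computation, angle effects left in.
#' * `calibrated3d` — `practical` followed by [apply_3d_calibration()] using
#'   angles transported from the point cloud and a fitted ratio model.
#'
#' @param protocol `"ideal"`, `"practical"` or `"calibrated3d"`.
#' @param cube reflectance [hsi_cube()] of the leaf in the protocol's pose.
#' @param cloud [point_cloud()] (required for `calibrated3d`).
#' @param proj_model `projection_model` (required for `calibrated3d`).
#' @param ratio_model fitted `ratio_model` (required for `calibrated3d`).
#' @param config a [leafcal_config()].
#' @return list with `ndvi` ([ndvi_map()]), `density` ([ndvi_density()] of
#'   valid pixels) and `report` (protocol, mean NDVI, pixel counts,
#'   provenance).
#' @export
run_protocol <- function(protocol = c("ideal", "practical", "calibrated3d"),
                         cube, cloud = NULL, proj_model = NULL,
                         ratio_model = NULL, config = leafcal_config()) {
  protocol <- match.arg(protocol)
  stopifnot(inherits(cube, "hsi_cube"))
  if (protocol == "calibrated3d") {
    for (nm in c("cloud", "proj_model", "ratio_model"))
      if (is.null(get(nm)))
        lc_abort(sprintf("protocol 'calibrated3d' requires `%s`.", nm),
                 "state_error")
  }
  mask <- segment_leaf(cube, threshold = config$seg_threshold,
                       wavelengths = config$red_edge)
  nd <- compute_ndvi(cube, mask, red = config$red, nir = config$nir)
  if (protocol == "calibrated3d") {
    ang <- fuse_angles(proj_model, cloud, dim(cube)[1:2],
                       window = config$window, theta_min = config$theta_min)
    nd <- apply_3d_calibration(nd, ang, ratio_model,
                               ratio_floor = config$ratio_floor)
  }
  dens <- ndvi_density(nd[!is.na(nd)])
  rep <- c(list(protocol = protocol, mean_ndvi = mean_ndvi(nd),
                n_valid = sum(!is.na(nd)), n_leaf = sum(mask)),
           version_and_provenance(config))
  list(ndvi = nd, density = dens, report = rep)
}

#' Package version, configuration hash and seed provenance
#'
#' Emitted into every protocol report so runs are attributable: the same
#' configuration and seed hash identically, a changed seed is flagged by a
#' different hash.
#'
#' @param config a [leafcal_config()].
#' @return list with `package`, `version`, `config_hash`, `seed`.
#' @export
version_and_provenance <- function(config = leafcal_config()) {
  list(package = "leafcal",
       version = as.character(utils::packageVersion("leafcal")),
       config_hash = rlang::hash(config),
       seed = config$seed)
}

#' Simulated three-protocol calibration experiment
#'
#' End-to-end comparison of the ideal, practical and 3D calibration
#' protocols on one synthetic leaf: a rotation experiment is simulated and
#' the species ratio model fitted; the same leaf (shared texture field) is
#' rendered flat (ideal) and curved (practical); the projection model is
#' fitted from the scene fiducials; and the curved scan is 3D-calibrated.
#' Protocols are compared by the L1 distance between their pixel-NDVI density
#' curves and by paired t-tests over patch means at `n_points` interior
#' points.
#'
#' @param profile a [species_profile()] (default corn, the arched-leaf case).
#' @param geometry curved-pose geometry (default a 12 mm arch).
#' @param seed integer seed driving all stochastic steps.
#' @param n_leaves leaves in the simulated rotation experiment (default 8).
#' @param n_points patch centers for the paired tests (default 22).
#' @param k patch pixel count (default 36).
#' @param config a [leafcal_config()].
#' @return list with the three protocol results (`ideal`, `practical`,
#'   `calibrated3d`), density distances to the ideal curve (`d_practical`,
#'   `d_calibrated3d`), paired t-tests (`t_ideal_practical`,
#'   `t_ideal_calibrated3d`, `t_calibrated3d_practical`), the patch-mean
#'   tibble and the fitted `ratio_model`.
#' @export
protocol_experiment <- function(profile = species_profile("corn"),
                                geometry = list(type = "arch"),
                                seed = 1L, n_leaves = 8L, n_points = 22L,
                                k = 36L, config = leafcal_config()) {
  seeds <- seed * 101L + 1:4
  rec <- simulate_rotation_experiment(profile, n_leaves, sigma = 0.01,
                                      seed = seeds[1L])
  rm <- fit_ratio_model(build_ratio_table(rec, reference = config$reference),
                        folds = config$svr_folds, cost = config$svr_cost,
                        epsilon = config$svr_epsilon, gamma = config$svr_gamma)
  flat_scene <- make_leaf_scene(profile,
                                list(type = "plane", theta = 0,
                                     side_mm = geometry$width_mm %||% 40),
                                seed = seeds[2L], texture_seed = seeds[4L])
  curved_scene <- make_leaf_scene(profile, geometry, seed = seeds[3L],
                                  texture_seed = seeds[4L])
  pm <- solve_projection(curved_scene$correspondences)

  ideal <- run_protocol("ideal", flat_scene$cube, config = config)
  practical <- run_protocol("practical", curved_scene$cube, config = config)
  cal3d <- run_protocol("calibrated3d", curved_scene$cube,
                        cloud = curved_scene$cloud, proj_model = pm,
                        ratio_model = rm, config = config)

  # deterministic interior patch centers, valid in all three maps
  half <- as.integer(ceiling(sqrt(k) / 2))
  ok <- !is.na(unclass(ideal$ndvi)) & !is.na(unclass(practical$ndvi)) &
    !is.na(unclass(cal3d$ndvi))
  ok <- boxsum2d(ok * 1, half) == (2L * half + 1L)^2 & ok
  idx <- which(ok, arr.ind = TRUE)
  if (nrow(idx) < n_points)
    lc_abort("too few interior pixels for the requested patch count.",
             "empty_error")
  centers <- idx[round(seq(1L, nrow(idx), length.out = n_points)), ,
                 drop = FALSE]
  pm_ideal <- patch_means(ideal$ndvi, centers, k = k)
  pm_prac <- patch_means(practical$ndvi, centers, k = k)
  pm_cal <- patch_means(cal3d$ndvi, centers, k = k)

  list(
    ideal = ideal, practical = practical, calibrated3d = cal3d,
    ratio_model = rm, projection_model = pm,
    d_practical = density_distance(practical$density, ideal$density),
    d_calibrated3d = density_distance(cal3d$density, ideal$density),
    t_ideal_practical = paired_ttest(pm_ideal$mean, pm_prac$mean),
    t_ideal_calibrated3d = paired_ttest(pm_ideal$mean, pm_cal$mean),
    t_calibrated3d_practical = paired_ttest(pm_cal$mean, pm_prac$mean),
    patches = tibble::tibble(row = pm_ideal$row, col = pm_ideal$col,
                             ideal = pm_ideal$mean, practical = pm_prac$mean,
                             calibrated3d = pm_cal$mean))
}
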