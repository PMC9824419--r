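#' Build the NDVI ratio table from rotation-experiment records
#'
#' Each scanned pose contributes `ratio = mean_ndvi / reference`, where the
#' reference is the same leaf's 0-degree (horizontal) NDVI. With
#' `reference = "per-orientation"` (default) each orientation sequence is
#' normalized by its own 0-degree scan, matching a protocol where every
#' orientation round starts horizontal; `"per-leaf"` divides by the mean of
#' all the leaf's 0-degree scans.
#'
#' @param records tibble with columns
#'   `leaf_id, species, orientation_deg, angle_deg, mean_ndvi`.
#' @param reference `"per-orientation"` or `"per-leaf"`.
#' @return tibble with an added `ratio` column, ordered by
#'   (leaf, orientation, angle); attribute `reference` records the convention.
#' @examples
#' rec <- tibble::tibble(leaf_id = 1, species = "soybean",
#'                       orientation_deg = 0, angle_deg = c(0, 30),
#'                       mean_ndvi = c(0.80, 0.84))
#' build_ratio_table(rec)$ratio # 1.00 1.05
#' @export
build_ratio_table <- function(records,
                              reference = c("per-orientation", "per-leaf")) {
  reference <- match.arg(reference)
  records <- tibble::as_tibble(records)
  need <- c("leaf_id", "species", "orientation_deg", "angle_deg", "mean_ndvi")
  if (!all(need %in% names(records)))
    lc_abort(sprintf("records need columns %s.", paste(need, collapse = ", ")),
             "dimension_error")
  grp <- if (reference == "per-orientation") c("leaf_id", "orientation_deg")
         else "leaf_id"
  out <- records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::mutate(.ref = mean(.data$mean_ndvi[.data$angle_deg == 0])) |>
    dplyr::ungroup()
  if (any(!is.finite(out$.ref))) {
    bad <- out |>
      dplyr::filter(!is.finite(.data$.ref)) |>
      dplyr::distinct(.data$leaf_id)
    lc_abort(sprintf(
      "incomplete protocol: no 0-degree reference scan for leaf %s.",
      paste(utils::head(bad$leaf_id, 3L), collapse = ", ")), "state_error")
  }
  out |>
    dplyr::mutate(ratio = .data$mean_ndvi / .data$.ref) |>
    dplyr::select(-".ref") |>
    dplyr::arrange(.data$leaf_id, .data$orientation_deg, .data$angle_deg) |>
    structure(reference = reference)
}

#' Venetian-blinds fold assignment
#'
#' Assigns every k-th ordered sample to the same fold, interleaving folds
#' across the dataset (sample i goes to fold `((i - 1) mod folds) + 1`).
#'
#' @param n number of samples.
#' @param folds number of folds (>= 2).
#' @return integer fold labels of length `n`.
#' @export
venetian_folds <- function(n, folds) {
  if (folds < 2L) lc_abort("`folds` must be >= 2.", "parameter_error")
  ((seq_len(n) - 1L) %% folds) + 1L
}

encode_features <- function(angle, orientation, enc = NULL) {
  # orientation enters as (sin, cos) so the regression sees the circle and
  # the 0-degree pose (where orientation is physically degenerate) is smooth
  X <- cbind(theta = angle,
             sin_a = sin(deg2rad(orientation)),
             cos_a = cos(deg2rad(orientation)))
  if (is.null(enc)) {
    ctr <- colMeans(X)
    scl <- apply(X, 2L, stats::sd)
    scl[scl < 1e-12] <- 1
    enc <- list(center = ctr, scale = scl)
  }
  list(X = sweep(sweep(X, 2L, enc$center), 2L, enc$scale, "/"), enc = enc)
}

#' Fit the angular NDVI-ratio model (support vector regression)
#'
#' Models `ratio = f(theta, alpha)` with an RBF-kernel epsilon-SVR, the tilt
#' angle and the periodically encoded orientation `(sin alpha, cos alpha)` as
#' predictors (features standardized internally). Generalization is scored by
#' venetian-blinds cross-validation: the table rows (ordered by leaf,
#' orientation, angle) are interleaved into `folds` folds, each fold is
#' predicted by a model trained on the others, and `cv_r2` is the R-squared
#' between measured and cross-validation-predicted ratios.
#'
#' @param table a [build_ratio_table()] result (columns `angle_deg`,
#'   `orientation_deg`, `ratio`; `species` if present is recorded).
#' @param folds venetian-blinds folds (default 5).
#' @param cost,epsilon SVR hyperparameters (defaults C = 10, epsilon = 0.01).
#' @param gamma RBF width; `"scale"` (default) uses
#'   `1 / (n_features * var(X))` on the standardized features.
#' @return A `ratio_model`: the fitted svm, hyperparameters, feature
#'   encoding, `cv_r2`, and the per-sample CV predictions (`cv_pred`).
#' @export
fit_ratio_model <- function(table, folds = 5L, cost = 10, epsilon = 0.01,
                            gamma = "scale") {
  table <- tibble::as_tibble(table)
  need <- c("angle_deg", "orientation_deg", "ratio")
  if (!all(need %in% names(table)))
    lc_abort(sprintf("ratio table needs columns %s.",
                     paste(need, collapse = ", ")), "dimension_error")
  if (length(unique(table$angle_deg)) < 2L ||
      length(unique(table$orientation_deg)) < 2L)
    lc_abort("need at least 2 distinct angles and 2 distinct orientations.",
             "degenerate_error")
  if (folds < 2L) lc_abort("`folds` must be >= 2.", "parameter_error")

  ef <- encode_features(table$angle_deg, table$orientation_deg)
  X <- ef$X; y <- table$ratio
  g <- if (identical(gamma, "scale")) 1 / (ncol(X) * max(var(as.numeric(X)), 1e-12))
       else gamma

  fold <- venetian_folds(nrow(X), folds)
  cv_pred <- rep(NA_real_, nrow(X))
  for (k in seq_len(folds)) {
    tr <- fold != k
    fit_k <- e1071::svm(X[tr, , drop = FALSE], y[tr], type = "eps-regression",
                        kernel = "radial", cost = cost, epsilon = epsilon,
                        gamma = g, scale = FALSE)
    cv_pred[!tr] <- predict(fit_k, X[!tr, , drop = FALSE])
  }
  cv_r2 <- 1 - sum((y - cv_pred)^2) / sum((y - mean(y))^2)

  fit <- e1071::svm(X, y, type = "eps-regression", kernel = "radial",
                    cost = cost, epsilon = epsilon, gamma = g, scale = FALSE)
  structure(list(
    svm = fit, species = if ("species" %in% names(table))
      as.character(table$species[1L]) else NA_character_,
    hyper = list(kernel = "radial", cost = cost, epsilon = epsilon,
                 gamma = g, folds = folds),
    encoding = ef$enc, cv_r2 = cv_r2, n = nrow(X),
    cv_pred = tibble::tibble(angle_deg = table$angle_deg,
                             orientation_deg = table$orientation_deg,
                             ratio = y, cv_pred = cv_pred),
    theta_range = range(table$angle_deg),
    sv = list(SV = fit$SV, coefs = as.numeric(fit$coefs), rho = fit$rho)),
    class = "ratio_model")
}

#' @export
print.ratio_model <- function(x, ...) {
  cat(sprintf(
    "<ratio_model> %s: RBF SVR (C=%g, eps=%g, gamma=%.4g), n=%d, CV R2=%.4f\n",
    x$species %||% "?", x$hyper$cost, x$hyper$epsilon, x$hyper$gamma, x$n,
    x$cv_r2))
  invisible(x)
}

#' Predict the NDVI ratio at given tilt angle and orientation
#'
#' Orientation is wrapped to `[0, 360)` through its periodic encoding; tilt
#' angles outside the fitted range trigger an extrapolation warning.
#'
#' @param model a fitted `ratio_model`.
#' @param theta tilt angle(s), degrees.
#' @param alpha orientation(s), degrees; recycled against `theta`.
#' @return numeric vector of predicted ratios.
#' @export
predict_ratio <- function(model, theta, alpha) {
  stopifnot(inherits(model, "ratio_model"))
  if (is.null(model$svm) && is.null(model$sv))
    lc_abort("ratio model is not fitted.", "state_error")
  k <- max(length(theta), length(alpha))
  theta <- rep_len(theta, k); alpha <- rep_len(alpha, k) %% 360
  if (any(theta < model$theta_range[1L] - 1e-9 |
          theta > model$theta_range[2L] + 1e-9))
    rlang::warn(sprintf(
      "predicting outside the fitted tilt range [%g, %g] deg (extrapolation).",
      model$theta_range[1L], model$theta_range[2L]))
  X <- encode_features(theta, alpha, enc = model$encoding)$X
  if (!is.null(model$svm)) {
    as.numeric(predict(model$svm, X))
  } else {
    # reloaded model: explicit RBF expansion over the stored support vectors
    SV <- model$sv$SV
    d2 <- outer(rowSums(X^2), rowSums(SV^2), "+") - 2 * X %*% t(SV)
    as.numeric(exp(-model$hyper$gamma * pmax(d2, 0)) %*% model$sv$coefs -
               model$sv$rho)
  }
}

#' Orientation-marginal ratio
#'
#' Mean predicted ratio over the orientation circle at given tilt angles;
#' used for pixels whose orientation is undefined (near-horizontal).
#'
#' @param model a fitted `ratio_model`.
#' @param theta tilt angle(s), degrees.
#' @param n_alpha number of orientation samples over `[0, 360)`.
#' @return numeric vector, same length as `theta`.
#' @export
marginal_ratio <- function(model, theta, n_alpha = 8L) {
  alphas <- seq(0, 360, length.out = n_alpha + 1L)[-(n_alpha + 1L)]
  rowMeans(vapply(alphas, function(a) predict_ratio(model, theta, a),
                  numeric(length(theta))))
}

#' Apply 3D calibration to an NDVI map
#'
#' Divides each valid pixel's NDVI by the ratio the model predicts for that
#' pixel's tilt angle and orientation, normalizing the measurement to the
#' flat-leaf (0-degree) standard. Pixels with undefined orientation use the
#' orientation-marginal ratio; pixels whose predicted ratio falls below
#' `ratio_floor` (an extrapolation signal: dividing by a near-zero ratio
#' would fabricate NDVI) are marked invalid. Calibrated values are clamped
#' into `[-1, 1]`.
#'
#' @param ndvi an [ndvi_map()].
#' @param angles an [angle_map()] of the same spatial shape.
#' @param model a fitted `ratio_model`.
#' @param ratio_floor smallest ratio accepted as a divisor (default 0.1).
#' @return The calibrated [ndvi_map()].
#' @export
apply_3d_calibration <- function(ndvi, angles, model, ratio_floor = 0.1) {
  stopifnot(inherits(ndvi, "ndvi_map"), inherits(angles, "angle_map"),
            inherits(model, "ratio_model"))
  if (!identical(dim(ndvi), dim(angles$theta)))
    lc_abort("NDVI map and angle map shapes differ.", "dimension_error")
  out <- matrix(NA_real_, nrow(ndvi), ncol(ndvi))
  ok <- !is.na(unclass(ndvi)) & angles$valid & !is.na(angles$theta)
  has_a <- ok & !is.na(angles$alpha)
  no_a <- ok & is.na(angles$alpha)
  ratio <- matrix(NA_real_, nrow(ndvi), ncol(ndvi))
  if (any(has_a))
    ratio[has_a] <- predict_ratio(model, angles$theta[has_a],
                                  angles$alpha[has_a])
  if (any(no_a))
    ratio[no_a] <- marginal_ratio(model, angles$theta[no_a])
  use <- ok & !is.na(ratio) & ratio >= ratio_floor
  out[use] <- pmin(1, pmax(-1, ndvi[use] / ratio[use]))
  ndvi_map(out)
}

#' Write / read a ratio model as JSON
#'
#' Stores species, hyperparameters, feature encoding, CV score and the full
#' support-vector expansion, so a reloaded model predicts identically
#' (through the explicit RBF kernel sum).
#'
#' @param model a fitted `ratio_model`.
#' @param path JSON path.
#' @export
write_ratio_model <- function(model, path) {
  stopifnot(inherits(model, "ratio_model"))
  jsonlite::write_json(list(
    species = model$species, hyper = model$hyper,
    encoding = list(center = as.numeric(model$encoding$center),
                    scale = as.numeric(model$encoding$scale)),
    cv_r2 = model$cv_r2, n = model$n, theta_range = model$theta_range,
    sv = list(SV = as.numeric(t(model$sv$SV)), n_sv = nrow(model$sv$SV),
              coefs = model$sv$coefs, rho = model$sv$rho)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ratio_model
#' @export
read_ratio_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  SV <- matrix(j$sv$SV, j$sv$n_sv, 3L, byrow = TRUE)
  colnames(SV) <- c("theta", "sin_a", "cos_a")
  enc <- list(center = stats::setNames(j$encoding$center, colnames(SV)),
              scale = stats::setNames(j$encoding$scale, colnames(SV)))
  structure(list(svm = NULL, species = j$species, hyper = j$hyper,
                 encoding = enc, cv_r2 = j$cv_r2, n = j$n, cv_pred = NULL,
                 theta_range = j$theta_range,
                 sv = list(SV = SV, coefs = j$sv$coefs, rho = j$sv$rho)),
            class = "ratio_model")
}
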