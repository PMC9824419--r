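#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted ratio model: per-sample cross-validation predictions
#'
#' @param x a `ratio_model`.
#' @param ... unused.
#' @return tibble with `angle_deg`, `orientation_deg`, `ratio`, `cv_pred`.
#' @export
tidy.ratio_model <- function(x, ...) {
  if (is.null(x$cv_pred))
    lc_abort("reloaded models carry no CV predictions to tidy.", "state_error")
  x$cv_pred
}

#' @rdname tidy.ratio_model
#' @return for `glance`: one-row tibble with species, n, cv_r2 and
#'   hyperparameters.
#' @export
glance.ratio_model <- function(x, ...) {
  tibble::tibble(species = x$species, n = x$n, cv_r2 = x$cv_r2,
                 n_sv = nrow(x$sv$SV), kernel = x$hyper$kernel,
                 cost = x$hyper$cost, epsilon = x$hyper$epsilon,
                 gamma = x$hyper$gamma, folds = x$hyper$folds)
}

#' Tidy a projection model: signed per-point reprojection residuals
#'
#' @param x a `projection_model` with fit statistics.
#' @param ... unused.
#' @export
tidy.projection_model <- function(x, ...) {
  if (is.null(x$fit_stats))
    lc_abort("model carries no fit statistics.", "state_error")
  x$fit_stats
}

#' @rdname tidy.projection_model
#' @export
glance.projection_model <- function(x, ...) {
  fs <- x$fit_stats
  tibble::tibble(model = x$model, gauge = x$gauge,
                 refined = !is.null(x$cheb),
                 n = if (is.null(fs)) NA_integer_ else nrow(fs),
                 rms = x$rms,
                 max_abs_du = if (is.null(fs)) NA_real_ else max(abs(fs$du)),
                 max_abs_dv = if (is.null(fs)) NA_real_ else max(abs(fs$dv)))
}

#' Heatmap of an NDVI map
#'
#' @param object an [ndvi_map()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ndvi_map <- function(object, ...) {
  idx <- which(!is.na(object), arr.ind = TRUE)
  df <- tibble::tibble(row = idx[, 1L], col = idx[, 2L],
                       ndvi = object[idx])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$ndvi)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(-1, 1) * max(abs(df$ndvi))) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column", y = "row", fill = "NDVI")
}

#' Probability density curve(s) of pixel NDVI
#'
#' @param object a `density_curve`, or pass several named curves via `...`
#'   to overlay protocols.
#' @param ... further named `density_curve` objects.
#' @return a ggplot.
#' @export
autoplot.density_curve <- function(object, ...) {
  curves <- c(list(object), list(...))
  nm <- names(curves)
  if (is.null(nm)) nm <- rep("", length(curves))
  nm[nm == ""] <- paste0("curve ", which(nm == ""))
  df <- dplyr::bind_rows(lapply(seq_along(curves), function(i)
    tibble::tibble(protocol = nm[i], ndvi = curves[[i]]$grid,
                   density = curves[[i]]$density)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ndvi, y = .data$density,
                                   color = .data$protocol)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "NDVI", y = "probability density")
}

#' Measured vs. predicted ratio surface of a fitted ratio model
#'
#' Plots the cross-validation predictions against tilt angle, one line per
#' orientation, over the measured ratios.
#'
#' @param object a `ratio_model` fitted in this session.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ratio_model <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$angle_deg, y = .data$ratio,
                                   color = factor(.data$orientation_deg))) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$cv_pred),
                       stat = "summary", fun = mean) +
    ggplot2::labs(x = "tilt angle (deg)", y = "NDVI ratio vs 0 deg",
                  color = "orientation (deg)",
                  title = sprintf("%s: CV R-squared = %.3f",
                                  object$species, object$cv_r2))
}

#' Tilt-angle heatmap of an angle map
#'
#' @param object an [angle_map()].
#' @param which `"theta"` or `"alpha"`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.angle_map <- function(object, which = c("theta", "alpha"), ...) {
  which <- match.arg(which)
  m <- object[[which]]
  idx <- base::which(!is.na(m), arr.ind = TRUE)
  df <- tibble::tibble(row = idx[, 1L], col = idx[, 2L], value = m[idx])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column", y = "row",
                  fill = if (which == "theta") "tilt (deg)"
                         else "orientation (deg)")
}
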