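#' Kernel density curve of pixel NDVI values
#'
#' Gaussian-kernel density on a 512-point grid spanning the data range plus 3
#' bandwidths on each side; `bandwidth = "auto"` uses Silverman's
#' rule of thumb. The returned curve integrates to 1 (trapezoid rule) to
#' within 1e-3.
#'
#' @param values numeric vector (>= 2 finite values).
#' @param bandwidth positive number or `"auto"`.
#' @return A `density_curve`: list with `grid`, `density`, `bandwidth`, `n`.
#' @export
ndvi_density <- function(values, bandwidth = "auto") {
  values <- values[is.finite(values)]
  if (length(values) < 2L)
    lc_abort("need at least 2 finite values for a density curve.",
             "empty_error")
  bw <- if (identical(bandwidth, "auto")) {
    if (stats::sd(values) < 1e-12)
      lc_abort("constant input: automatic bandwidth is degenerate.",
               "degenerate_error")
    stats::bw.nrd0(values)
  } else {
    if (!is_scalar_number(bandwidth) || bandwidth <= 0)
      lc_abort("`bandwidth` must be a positive number or \"auto\".",
               "parameter_error")
    bandwidth
  }
  d <- stats::density(values, bw = bw, kernel = "gaussian", n = 512L,
                      from = min(values) - 3 * bw, to = max(values) + 3 * bw)
  structure(list(grid = d$x, density = d$y, bandwidth = bw,
                 n = length(values)),
            class = "density_curve")
}

#' @export
print.density_curve <- function(x, ...) {
  cat(sprintf("<density_curve> n=%d, bw=%.4g, grid [%.4g, %.4g] (512 pts)\n",
              x$n, x$bandwidth, min(x$grid), max(x$grid)))
  invisible(x)
}

#' L1 distance between two density curves
#'
#' Both curves are re-evaluated (linear interpolation, zero outside support)
#' on a common 1024-point grid spanning their union range; the integral of
#' the absolute difference is returned. 0 means identical distributions, 2
#' disjoint ones (total variation x 2).
#'
#' @param a,b `density_curve` objects.
#' @return scalar in `[0, 2]`.
#' @export
density_distance <- function(a, b) {
  stopifnot(inherits(a, "density_curve"), inherits(b, "density_curve"))
  lo <- min(a$grid, b$grid); hi <- max(a$grid, b$grid)
  g <- seq(lo, hi, length.out = 1024L)
  fa <- stats::approx(a$grid, a$density, g, yleft = 0, yright = 0)$y
  fb <- stats::approx(b$grid, b$density, g, yleft = 0, yright = 0)$y
  trapz(g, abs(fa - fb))
}

#' Patch means around selected points
#'
#' Averages NDVI over a `sqrt(k) x sqrt(k)` window centered at each point
#' (for even window sides the center sits at position
#' `(side/2, side/2)` of the window, so k = 36 uses rows `r-2 ... r+3`).
#' Windows must lie within the image; windows with fewer than 50% valid
#' pixels are flagged.
#'
#' @param ndvi an [ndvi_map()].
#' @param centers two-column matrix or data frame of (row, col) centers,
#'   1-based.
#' @param k window pixel count; must be a perfect square (default 36).
#' @return tibble with `row`, `col`, `mean`, `n_valid`, `flagged`.
#' @export
patch_means <- function(ndvi, centers, k = 36L) {
  stopifnot(inherits(ndvi, "ndvi_map"))
  side <- sqrt(k)
  if (side != round(side))
    lc_abort("`k` must be a perfect square.", "parameter_error")
  side <- as.integer(side)
  lo <- -(ceiling(side / 2) - 1L); hi <- floor(side / 2)
  centers <- as.matrix(centers)[, 1:2, drop = FALSE]
  res <- apply(centers, 1L, function(rc) {
    r <- rc[1L]; c2 <- rc[2L]
    if (r + lo < 1L || r + hi > nrow(ndvi) || c2 + lo < 1L ||
        c2 + hi > ncol(ndvi))
      lc_abort(sprintf("patch at (%d, %d) extends outside the image.", r, c2),
               "range_error")
    w <- ndvi[(r + lo):(r + hi), (c2 + lo):(c2 + hi)]
    nv <- sum(!is.na(w))
    c(mean = if (nv) mean(w, na.rm = TRUE) else NA_real_, n_valid = nv)
  })
  tibble::tibble(row = centers[, 1L], col = centers[, 2L],
                 mean = unname(res["mean", ]),
                 n_valid = as.integer(unname(res["n_valid", ])),
                 flagged = unname(res["n_valid", ]) < k / 2)
}

#' Two-sided paired t-test
#'
#' Thin wrapper around [stats::t.test()] on the paired differences. Identical
#' samples (all differences exactly zero) return `t = 0, p = 1`; a constant
#' non-zero difference has no variance to test against and raises a
#' degenerate error.
#'
#' @param a,b numeric vectors of equal length >= 2.
#' @return list with `t`, `p`, `df`, `mean_diff`.
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b))
    lc_abort("paired samples must have equal length.", "dimension_error")
  if (length(a) < 2L)
    lc_abort("need at least 2 pairs.", "empty_error")
  d <- a - b
  if (all(d == 0))
    return(list(t = 0, p = 1, df = length(d) - 1L, mean_diff = 0))
  if (stats::sd(d) < 1e-15)
    lc_abort("paired differences are constant: zero variance.",
             "degenerate_error")
  ht <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), mean_diff = unname(ht$estimate))
}

#' Balanced two-way ANOVA with interaction
#'
#' Classic fixed-effects two-way analysis of variance for a balanced design:
#' `angle` (reported as "Columns"), `orientation` (reported as "Rows"), their
#' interaction, and the within-cell error. Unbalanced designs raise an error
#' rather than silently choosing a sums-of-squares type, and a single
#' replicate per cell leaves no error degrees of freedom.
#'
#' @param data long-format data frame.
#' @param response,angle,orientation column names (defaults `"ndvi"`,
#'   `"angle_deg"`, `"orientation_deg"`).
#' @return An `anova_table` tibble with columns
#'   `Source, SS, df, MS, F, p` and rows Columns, Rows, Interaction, Error,
#'   Total.
#' @examples
#' df <- expand.grid(angle_deg = c(0, 10), orientation_deg = c(0, 45),
#'                   rep = 1:3)
#' df$ndvi <- 0.8 + 0.01 * df$rep
#' two_way_anova(df)
#' @export
two_way_anova <- function(data, response = "ndvi", angle = "angle_deg",
                          orientation = "orientation_deg") {
  data <- as.data.frame(data)
  for (cn in c(response, angle, orientation))
    if (!cn %in% names(data))
      lc_abort(sprintf("column '%s' not found.", cn), "dimension_error")
  A <- factor(data[[angle]])
  B <- factor(data[[orientation]])
  y <- data[[response]]
  if (any(!is.finite(y)))
    lc_abort("response contains non-finite values.", "value_error")
  counts <- table(A, B)
  if (length(unique(as.vector(counts))) != 1L || any(counts == 0))
    lc_abort("design is unbalanced: equal replicates per cell are required.",
             "degenerate_error")
  r <- as.vector(counts)[1L]
  if (r == 1L)
    lc_abort("one replicate per cell leaves no error degrees of freedom.",
             "degenerate_error")
  fit <- stats::aov(y ~ A * B)
  tab <- summary(fit)[[1L]]
  ss <- tab[["Sum Sq"]]; df <- tab[["Df"]]
  ms <- tab[["Mean Sq"]]; f <- tab[["F value"]]; p <- tab[["Pr(>F)"]]
  out <- tibble::tibble(
    Source = c("Columns", "Rows", "Interaction", "Error", "Total"),
    SS = c(ss, sum(ss)),
    df = c(df, sum(df)),
    MS = c(ms, NA_real_),
    F = c(f, NA_real_),
    p = c(p, NA_real_))
  out$MS[4L] <- ss[4L] / df[4L]
  out$F[4L] <- NA_real_; out$p[4L] <- NA_real_
  class(out) <- c("anova_table", class(out))
  out
}

#' Write an ANOVA table as CSV (Source, SS, df, MS, F, Prob>F order)
#'
#' @param tab an `anova_table`.
#' @param path CSV path.
#' @export
write_anova_csv <- function(tab, path) {
  df <- as.data.frame(tab)
  names(df) <- c("Source", "SS", "df", "MS", "F", "Prob>F")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
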