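#' Hyperspectral cube
#'
#' Container for a rows x cols x bands hyperspectral image with its wavelength
#' axis. `kind = "raw"` holds sensor digital numbers; `kind = "reflectance"`
#' holds white/dark calibrated reflectance (see [white_calibrate()]).
#'
#' @param data numeric array, rows x cols x bands, non-negative.
#' @param wavelengths strictly increasing numeric vector of band centers (nm),
#'   length equal to the band dimension.
#' @param kind `"raw"` or `"reflectance"`.
#' @return An object of class `hsi_cube`.
#' @examples
#' cube <- hsi_cube(array(0.5, c(4, 3, 2)), c(680, 800), kind = "reflectance")
#' dim(cube$data)
#' @export
hsi_cube <- function(data, wavelengths, kind = c("raw", "reflectance")) {
  kind <- match.arg(kind)
  if (!is.array(data) || length(dim(data)) != 3L)
    lc_abort("`data` must be a rows x cols x bands array.", "dimension_error")
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != dim(data)[3L])
    lc_abort(sprintf(
      "wavelength axis has %d entries but the cube has %d bands.",
      length(wavelengths), dim(data)[3L]), "dimension_error")
  if (any(diff(wavelengths) <= 0))
    lc_abort("wavelengths must be strictly increasing.", "value_error")
  if (kind == "reflectance" && any(!is.finite(data) & !is.na(data)))
    lc_abort("reflectance cube contains non-finite values.", "value_error")
  structure(list(data = data, wavelengths = wavelengths, kind = kind),
            class = "hsi_cube")
}

#' @export
print.hsi_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hsi_cube> %d x %d pixels, %d bands (%.1f-%.1f nm), kind = %s\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths), x$kind))
  invisible(x)
}

#' @export
dim.hsi_cube <- function(x) dim(x$data)

#' White/dark reference pair
#'
#' The white panel and dark-current references used for reflectance
#' calibration. Each may be a full cube matching the raw image, or a
#' cols x bands plane (a pushbroom reference strip averaged along the scan
#' axis), in which case it is replicated over scan lines.
#'
#' @param white positive reference values (cube array or cols x bands matrix).
#' @param dark dark-current values, same shape as `white`.
#' @return An object of class `reference_pair`.
#' @export
reference_pair <- function(white, dark) {
  if (!identical(dim(white), dim(dark)))
    lc_abort("white and dark references must have the same shape.",
             "dimension_error")
  structure(list(white = white, dark = dark), class = "reference_pair")
}

expand_reference <- function(ref, d) {
  # ref: array (rows x cols x bands) or matrix (cols x bands) -> full array
  if (is.matrix(ref)) {
    if (!identical(dim(ref), c(d[2L], d[3L])))
      lc_abort(sprintf(
        "reference plane is %d x %d but cube needs cols x bands = %d x %d.",
        nrow(ref), ncol(ref), d[2L], d[3L]), "dimension_error")
    aperm(array(rep(ref, each = d[1L]), c(d[1L], d[2L], d[3L])), c(1L, 2L, 3L))
  } else {
    if (!identical(dim(ref), d))
      lc_abort("reference cube shape does not match the raw cube.",
               "dimension_error")
    ref
  }
}

#' Reflectance calibration against white and dark references
#'
#' Converts raw digital numbers to reflectance as
#' `(raw - dark) / (white - dark)`, elementwise. Elements whose reference
#' difference `white - dark` falls below `eps` are marked invalid (`NA`)
#' rather than aborting the scan (`on_degenerate = "mark"`, the default), or
#' raise a degenerate-reference error naming the first offending
#' column/band (`on_degenerate = "error"`).
#'
#' @param raw an [hsi_cube()] of kind `"raw"`.
#' @param refs a [reference_pair()].
#' @param on_degenerate `"mark"` or `"error"`.
#' @param eps smallest usable reference difference (default `1e-9`).
#' @return An [hsi_cube()] of kind `"reflectance"`.
#' @examples
#' raw <- hsi_cube(array(120, c(2, 2, 1)), 680)
#' refs <- reference_pair(array(220, c(2, 2, 1)), array(20, c(2, 2, 1)))
#' white_calibrate(raw, refs)$data[1, 1, 1] # 0.5
#' @export
white_calibrate <- function(raw, refs, on_degenerate = c("mark", "error"),
                            eps = 1e-9) {
  on_degenerate <- match.arg(on_degenerate)
  stopifnot(inherits(raw, "hsi_cube"), inherits(refs, "reference_pair"))
  if (raw$kind == "reflectance")
    lc_abort("cube is already reflectance-calibrated; refusing to calibrate twice.",
             "state_error")
  d <- dim(raw$data)
  white <- expand_reference(refs$white, d)
  dark <- expand_reference(refs$dark, d)
  denom <- white - dark
  bad <- denom < eps
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    msg <- sprintf(
      "%d element(s) with white - dark < %g (first at column %d, band %d = %.1f nm).",
      sum(bad), eps, idx[2L], idx[3L], raw$wavelengths[idx[3L]])
    if (on_degenerate == "error")
      lc_abort(paste("degenerate white reference:", msg), "degenerate_error")
    rlang::warn(paste("marking invalid:", msg))
  }
  refl <- (raw$data - dark) / denom
  refl[bad] <- NA_real_
  out <- hsi_cube(array(0, d), raw$wavelengths, kind = "reflectance")
  out$data <- refl
  out
}

#' Extract the band plane nearest a wavelength
#'
#' Named wavelengths (680, 732, 800 nm) rarely coincide with sampled band
#' centers; the nearest center is used and reported via attributes
#' `wavelength` (the actual center) and `band` (its index).
#'
#' @param cube an [hsi_cube()].
#' @param wavelength_nm requested wavelength; must lie within the axis range.
#' @return rows x cols numeric matrix with attributes `wavelength` and `band`.
#' @export
band_at <- function(cube, wavelength_nm) {
  stopifnot(inherits(cube, "hsi_cube"))
  wl <- cube$wavelengths
  if (wavelength_nm < min(wl) || wavelength_nm > max(wl))
    lc_abort(sprintf("wavelength %.1f nm outside axis range [%.1f, %.1f] nm.",
                     wavelength_nm, min(wl), max(wl)), "range_error")
  i <- which.min(abs(wl - wavelength_nm))
  plane <- cube$data[, , i]
  attr(plane, "wavelength") <- wl[i]
  attr(plane, "band") <- i
  plane
}

#' Otsu threshold of a numeric sample
#'
#' Bimodal histogram split maximizing between-class variance; used by
#' [segment_leaf()] when `threshold = "auto"`.
#'
#' @param values numeric vector.
#' @param nbins number of histogram bins.
#' @return the threshold value.
#' @export
otsu_threshold <- function(values, nbins = 256L) {
  values <- values[is.finite(values)]
  if (length(unique(values)) < 2L)
    lc_abort("cannot pick an automatic threshold from a constant sample.",
             "degenerate_error")
  br <- seq(min(values), max(values), length.out = nbins + 1L)
  h <- tabulate(findInterval(values, br, rightmost.closed = TRUE), nbins)
  mids <- (br[-1L] + br[-length(br)]) / 2
  w <- cumsum(h); m <- cumsum(h * mids)
  n <- w[nbins]; mt <- m[nbins]
  w0 <- w[-nbins]; w1 <- n - w0
  ok <- w0 > 0 & w1 > 0
  between <- rep(-Inf, nbins - 1L)
  between[ok] <- (mt * w0[ok] - n * m[-nbins][ok])^2 / (w0[ok] * w1[ok])
  mids[which.max(between)]
}

#' Red-edge leaf segmentation
#'
#' Separates leaf from background by thresholding the red-edge normalized
#' difference `(R732 - R680) / (R732 + R680)`: green vegetation shows a steep
#' reflectance rise between 680 and 732 nm that backgrounds lack. With
#' `threshold = "auto"` an Otsu split of the index histogram is used.
#'
#' @param cube reflectance [hsi_cube()] whose axis covers 680 and 732 nm.
#' @param threshold numeric threshold on the red-edge index, or `"auto"`.
#' @param wavelengths the red-edge pair, default `c(680, 732)` nm.
#' @return A logical rows x cols matrix of class `leaf_mask` with attribute
#'   `threshold` (the value actually used).
#' @export
segment_leaf <- function(cube, threshold = "auto", wavelengths = c(680, 732)) {
  stopifnot(inherits(cube, "hsi_cube"))
  if (cube$kind != "reflectance")
    lc_abort("segmentation needs a reflectance cube; calibrate first.",
             "state_error")
  wl <- cube$wavelengths
  if (min(wavelengths) < min(wl) || max(wavelengths) > max(wl))
    lc_abort(sprintf("axis [%.1f, %.1f] nm does not cover the red-edge pair %s nm.",
                     min(wl), max(wl), paste(wavelengths, collapse = "/")),
             "coverage_error")
  r0 <- band_at(cube, wavelengths[1L])
  r1 <- band_at(cube, wavelengths[2L])
  s <- r1 + r0
  idx <- ifelse(is.na(s) | s < 1e-9, 0, (r1 - r0) / s)
  thr <- if (identical(threshold, "auto")) otsu_threshold(as.vector(idx))
         else threshold
  mask <- idx > thr
  structure(mask, class = c("leaf_mask", class(mask)), threshold = thr)
}

#' Per-pixel NDVI
#'
#' `NDVI = (NIR - RED) / (NIR + RED)` with RED and NIR the reflectance planes
#' nearest 680 and 800 nm. Pixels outside `mask` or with `NIR + RED` below
#' machine guard `1e-9` are invalid (`NA`).
#'
#' @param cube reflectance [hsi_cube()] covering 680 and 800 nm.
#' @param mask optional [segment_leaf()] mask; `NULL` computes all pixels.
#' @param red,nir wavelengths (nm) of the red and near-infrared bands.
#' @return rows x cols numeric matrix of class `ndvi_map`; `NA` = invalid.
#' @examples
#' cube <- hsi_cube(array(c(0.1, 0.8), c(1, 1, 2)), c(680, 800), "reflectance")
#' compute_ndvi(cube)[1, 1] # 0.7778
#' @export
compute_ndvi <- function(cube, mask = NULL, red = 680, nir = 800) {
  stopifnot(inherits(cube, "hsi_cube"))
  if (cube$kind != "reflectance")
    lc_abort("NDVI needs a reflectance cube; calibrate first.", "state_error")
  wl <- cube$wavelengths
  if (red < min(wl) || nir > max(wl))
    lc_abort(sprintf("axis [%.1f, %.1f] nm does not cover %g and %g nm.",
                     min(wl), max(wl), red, nir), "coverage_error")
  R <- band_at(cube, red)
  N <- band_at(cube, nir)
  s <- N + R
  v <- (N - R) / s
  v[!is.finite(s) | s < 1e-9] <- NA_real_
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(R)))
      lc_abort("mask shape does not match the cube's spatial shape.",
               "dimension_error")
    v[!mask] <- NA_real_
  }
  ndvi_map(v)
}

#' NDVI map constructor
#'
#' @param values rows x cols numeric matrix in `[-1, 1]`; `NA` marks invalid
#'   pixels.
#' @return object of class `ndvi_map`.
#' @export
ndvi_map <- function(values) {
  if (!is.matrix(values))
    lc_abort("`values` must be a matrix.", "dimension_error")
  ok <- is.na(values) | (values >= -1 & values <= 1)
  if (!all(ok))
    lc_abort("valid NDVI values must lie in [-1, 1].", "value_error")
  structure(values, class = c("ndvi_map", "matrix", "array"))
}

#' @export
print.ndvi_map <- function(x, ...) {
  n <- sum(!is.na(x))
  cat(sprintf("<ndvi_map> %d x %d, %d valid pixels%s\n", nrow(x), ncol(x), n,
              if (n) sprintf(", mean %.4f", mean(x, na.rm = TRUE)) else ""))
  invisible(x)
}

#' Mean NDVI over valid pixels
#'
#' The per-leaf summary: all valid pixel NDVIs averaged into one value.
#'
#' @param ndvi an [ndvi_map()].
#' @return scalar mean.
#' @export
mean_ndvi <- function(ndvi) {
  v <- ndvi[!is.na(ndvi)]
  if (length(v) == 0L)
    lc_abort("no valid NDVI pixels to average.", "empty_error")
  mean(v)
}
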