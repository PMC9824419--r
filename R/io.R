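#' Read an ENVI-style hyperspectral cube
#'
#' Parses an ASCII ENVI header (`samples`, `lines`, `bands`, `interleave`,
#' `data type`, `wavelength = {...}`) and its binary payload. Supported data
#' types: 2 (int16), 4 (float32), 5 (float64), 12 (uint16); interleaves BIL,
#' BSQ and BIP; little-endian byte order.
#'
#' @param header path to the `.hdr` file (the payload is the same path without
#'   `.hdr`, or with `.dat`/`.img`/`.bil` extension).
#' @param kind cube kind to tag, `"raw"` by default.
#' @return An [hsi_cube()].
#' @export
read_envi <- function(header, kind = "raw") {
  if (!file.exists(header))
    lc_abort(sprintf("header file not found: %s", header), "io_error")
  txt <- readLines(header, warn = FALSE)
  body <- paste(txt, collapse = "\n")
  getval <- function(key) {
    m <- regmatches(body, regexpr(paste0("(?mi)^\\s*", key, "\\s*=\\s*([^\\n{]+)"),
                                  body, perl = TRUE))
    if (!length(m)) return(NULL)
    trimws(sub(paste0("(?i)^\\s*", key, "\\s*=\\s*"), "", m, perl = TRUE))
  }
  samples <- as.integer(getval("samples"))
  lines_n <- as.integer(getval("lines"))
  bands <- as.integer(getval("bands"))
  if (any(is.na(c(samples, lines_n, bands))))
    lc_abort("header is missing samples/lines/bands.", "io_error")
  interleave <- tolower(getval("interleave") %||% "bil")
  dtype <- as.integer(getval("data type") %||% "4")
  border <- as.integer(getval("byte order") %||% "0")
  if (!is.na(border) && border != 0L)
    lc_abort("only little-endian (byte order = 0) payloads are supported.",
             "io_error")
  wlm <- regmatches(body, regexpr("wavelength\\s*=\\s*\\{[^}]*\\}", body,
                                  perl = TRUE))
  if (!length(wlm))
    lc_abort("header has no wavelength = {...} block.", "io_error")
  wl <- as.numeric(strsplit(gsub("^[^{]*\\{|\\}", "", wlm), ",")[[1L]])
  if (length(wl) != bands)
    lc_abort("wavelength list length does not match bands.", "io_error")

  stem <- sub("\\.hdr$", "", header, ignore.case = TRUE)
  cand <- c(stem, paste0(stem, c(".dat", ".img", ".bil", ".bin")))
  payload <- cand[file.exists(cand)][1L]
  if (is.na(payload))
    lc_abort(sprintf("binary payload for %s not found.", header), "io_error")

  n <- samples * lines_n * bands
  spec <- switch(as.character(dtype),
    "2" = list(what = integer(), size = 2L, signed = TRUE),
    "4" = list(what = numeric(), size = 4L, signed = TRUE),
    "5" = list(what = numeric(), size = 8L, signed = TRUE),
    "12" = list(what = integer(), size = 2L, signed = FALSE),
    lc_abort(sprintf("unsupported ENVI data type %d.", dtype), "io_error"))
  con <- file(payload, "rb"); on.exit(close(con))
  raw_v <- readBin(con, spec$what, n = n, size = spec$size,
                   signed = spec$signed, endian = "little")
  if (length(raw_v) != n)
    lc_abort("payload shorter than samples * lines * bands.", "io_error")
  raw_v <- as.numeric(raw_v)

  # assemble rows(=lines) x cols(=samples) x bands
  a <- switch(interleave,
    bsq = aperm(array(raw_v, c(samples, lines_n, bands)), c(2L, 1L, 3L)),
    bil = aperm(array(raw_v, c(samples, bands, lines_n)), c(3L, 1L, 2L)),
    bip = aperm(array(raw_v, c(bands, samples, lines_n)), c(3L, 2L, 1L)),
    lc_abort(sprintf("unsupported interleave '%s'.", interleave), "io_error"))
  hsi_cube(a, wl, kind = kind)
}

#' Write an ENVI-style cube (float32 payload)
#'
#' @param cube an [hsi_cube()].
#' @param stem output path stem; writes `<stem>.hdr` and `<stem>.dat`.
#' @param interleave `"bil"`, `"bsq"` or `"bip"`.
#' @return `stem`, invisibly.
#' @export
write_envi <- function(cube, stem, interleave = c("bil", "bsq", "bip")) {
  interleave <- match.arg(interleave)
  stopifnot(inherits(cube, "hsi_cube"))
  d <- dim(cube$data)
  hdr <- c("ENVI",
           sprintf("samples = %d", d[2L]),
           sprintf("lines = %d", d[1L]),
           sprintf("bands = %d", d[3L]),
           "data type = 4",
           sprintf("interleave = %s", interleave),
           "byte order = 0",
           sprintf("wavelength = {%s}",
                   paste(format(cube$wavelengths, trim = TRUE), collapse = ", ")))
  writeLines(hdr, paste0(stem, ".hdr"))
  v <- switch(interleave,
    bsq = aperm(cube$data, c(2L, 1L, 3L)),
    bil = aperm(cube$data, c(2L, 3L, 1L)),
    bip = aperm(cube$data, c(3L, 2L, 1L)))
  con <- file(paste0(stem, ".dat"), "wb"); on.exit(close(con))
  writeBin(as.numeric(v), con, size = 4L, endian = "little")
  invisible(stem)
}

#' Write / read an NDVI map as flat float32 binary with a JSON sidecar
#'
#' The payload is row-major float32 with NaN marking invalid pixels; the
#' sidecar records shape, dtype and order.
#'
#' @param ndvi an [ndvi_map()].
#' @param stem output stem; writes `<stem>.bin` and `<stem>.json`.
#' @return `stem` invisibly (write) or an [ndvi_map()] (read).
#' @export
write_ndvi <- function(ndvi, stem) {
  stopifnot(inherits(ndvi, "ndvi_map"))
  v <- as.numeric(t(unclass(ndvi))) # row-major
  v[is.na(v)] <- NaN
  con <- file(paste0(stem, ".bin"), "wb")
  writeBin(v, con, size = 4L, endian = "little"); close(con)
  jsonlite::write_json(
    list(rows = nrow(ndvi), cols = ncol(ndvi), dtype = "float32",
         order = "row-major", invalid = "NaN"),
    paste0(stem, ".json"), auto_unbox = TRUE)
  invisible(stem)
}

#' @rdname write_ndvi
#' @export
read_ndvi <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  con <- file(paste0(stem, ".bin"), "rb"); on.exit(close(con))
  v <- readBin(con, numeric(), n = meta$rows * meta$cols, size = 4L,
               endian = "little")
  m <- t(matrix(v, meta$cols, meta$rows))
  m[is.nan(m)] <- NA_real_
  ndvi_map(m)
}

#' Write an NDVI map as CSV (long format: row, col, ndvi; valid pixels only)
#'
#' @param ndvi an [ndvi_map()].
#' @param path output CSV path.
#' @export
write_ndvi_csv <- function(ndvi, path) {
  idx <- which(!is.na(ndvi), arr.ind = TRUE)
  utils::write.csv(
    data.frame(row = idx[, 1L], col = idx[, 2L], ndvi = ndvi[idx]),
    path, row.names = FALSE)
  invisible(path)
}

#' Read corner correspondences from CSV
#'
#' Expects the header `u,v,x,y,z`: image row and column (pixels) against
#' ground coordinates (meters, depth-camera frame). Coordinates produced by
#' 1-based detection tools are shifted with `origin = 1`.
#'
#' @param path CSV path.
#' @param origin 0 or 1; pixel origin convention of the file. Internally all
#'   coordinates are 0-based with pixel centers at integers.
#' @return tibble with columns `u, v, x, y, z`.
#' @export
read_correspondences <- function(path, origin = 0) {
  df <- utils::read.csv(path)
  need <- c("u", "v", "x", "y", "z")
  if (!all(need %in% names(df)))
    lc_abort("correspondence CSV must have columns u,v,x,y,z.", "io_error")
  if (!origin %in% c(0, 1))
    lc_abort("`origin` must be 0 or 1.", "parameter_error")
  df$u <- df$u - origin
  df$v <- df$v - origin
  tibble::as_tibble(df[need])
}

#' Read / write organized point clouds in PLY format
#'
#' Supports `ascii` and `binary_little_endian` PLY with float or double
#' `x, y, z` vertex properties (and optional uchar `red, green, blue`). The
#' organized grid shape is taken from `comment width <W>` / `comment height
#' <H>` lines, or from a `<path>.json` sidecar with fields `height`, `width`.
#' Non-finite coordinates mark invalid points.
#'
#' @param path PLY file path.
#' @return A [point_cloud()].
#' @export
read_ply <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  hdr <- character(); repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln)) lc_abort("unterminated PLY header.", "io_error")
    hdr <- c(hdr, ln)
    if (identical(trimws(ln), "end_header")) break
  }
  if (!identical(trimws(hdr[1L]), "ply"))
    lc_abort("not a PLY file.", "io_error")
  fmt <- strsplit(trimws(grep("^format", hdr, value = TRUE)[1L]), "\\s+")[[1L]][2L]
  nv <- as.integer(sub(".*vertex\\s+", "",
                       grep("^element vertex", hdr, value = TRUE)[1L]))
  props <- grep("^property", hdr, value = TRUE)
  pp <- do.call(rbind, strsplit(trimws(props), "\\s+"))
  ptype <- pp[, 2L]; pname <- pp[, 3L]
  sizes <- c(float = 4L, float32 = 4L, double = 8L, float64 = 8L,
             uchar = 1L, uint8 = 1L, char = 1L, int8 = 1L,
             short = 2L, ushort = 2L, int = 4L, uint = 4L, int32 = 4L)
  h <- w <- NA_integer_
  cm <- grep("^comment (width|height)", hdr, value = TRUE)
  for (c1 in cm) {
    kv <- strsplit(trimws(c1), "\\s+")[[1L]]
    if (kv[2L] == "width") w <- as.integer(kv[3L])
    if (kv[2L] == "height") h <- as.integer(kv[3L])
  }
  if (is.na(h) || is.na(w)) {
    sc <- paste0(path, ".json")
    if (file.exists(sc)) {
      meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
      h <- as.integer(meta$height); w <- as.integer(meta$width)
    }
  }
  if (is.na(h) || is.na(w))
    lc_abort("organized grid shape not found (no width/height comments or sidecar).",
             "io_error")
  if (h * w != nv)
    lc_abort(sprintf("grid %d x %d does not match %d vertices.", h, w, nv),
             "dimension_error")

  if (fmt == "ascii") {
    txt <- readLines(con, n = nv)
    vals <- utils::read.table(text = txt, nrows = nv)
    names(vals) <- pname
  } else if (fmt == "binary_little_endian") {
    rec <- sum(sizes[ptype])
    blob <- readBin(con, "raw", n = nv * rec)
    vals <- as.data.frame(matrix(0, nv, length(pname)))
    names(vals) <- pname
    off <- 0L
    for (k in seq_along(pname)) {
      sz <- sizes[[ptype[k]]]
      pos <- as.vector(outer(seq_len(sz), (seq_len(nv) - 1L) * rec, "+")) + off
      bytes <- blob[pos]
      vals[[k]] <- if (ptype[k] %in% c("float", "float32", "double", "float64"))
        readBin(bytes, numeric(), n = nv, size = sz, endian = "little")
      else readBin(bytes, integer(), n = nv, size = sz, signed = sz > 1L,
                   endian = "little")
      off <- off + sz
    }
  } else lc_abort(sprintf("unsupported PLY format '%s'.", fmt), "io_error")

  shape <- function(v) matrix(v, nrow = h, ncol = w, byrow = TRUE)
  col <- NULL
  if (all(c("red", "green", "blue") %in% pname))
    col <- array(c(shape(vals$red), shape(vals$green), shape(vals$blue)),
                 c(h, w, 3L))
  point_cloud(shape(vals$x), shape(vals$y), shape(vals$z), color = col)
}

#' @rdname read_ply
#' @param cloud a [point_cloud()] to write.
#' @param format `"binary_little_endian"` (default) or `"ascii"`.
#' @export
write_ply <- function(cloud, path, format = c("binary_little_endian", "ascii")) {
  format <- match.arg(format)
  stopifnot(inherits(cloud, "point_cloud"))
  h <- nrow(cloud$z); w <- ncol(cloud$z)
  xs <- as.numeric(t(cloud$x)); ys <- as.numeric(t(cloud$y))
  zs <- as.numeric(t(cloud$z))
  inval <- !as.logical(t(cloud$valid))
  xs[inval] <- NaN; ys[inval] <- NaN; zs[inval] <- NaN
  hdr <- c("ply", paste("format", format, "1.0"),
           sprintf("comment height %d", h), sprintf("comment width %d", w),
           sprintf("element vertex %d", h * w),
           "property float x", "property float y", "property float z",
           "end_header")
  if (format == "ascii") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(hdr, con)
    utils::write.table(data.frame(xs, ys, zs), con, row.names = FALSE,
                       col.names = FALSE)
  } else {
    con <- file(path, "wb"); on.exit(close(con))
    writeLines(hdr, con)
    inter <- as.numeric(rbind(xs, ys, zs))
    writeBin(inter, con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Read / write rotation-experiment records as CSV
#'
#' Long format with header
#' `leaf_id,species,orientation_deg,angle_deg,mean_ndvi` (plus `ratio` for
#' ratio tables).
#'
#' @param path CSV path.
#' @return tibble of rotation records.
#' @export
read_rotation_records <- function(path) {
  df <- utils::read.csv(path)
  need <- c("leaf_id", "species", "orientation_deg", "angle_deg", "mean_ndvi")
  if (!all(need %in% names(df)))
    lc_abort(sprintf("rotation CSV needs columns %s.", paste(need, collapse = ",")),
             "io_error")
  tibble::as_tibble(df)
}

#' @rdname read_rotation_records
#' @param records tibble of records (or ratio table) to write.
#' @export
write_rotation_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}
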