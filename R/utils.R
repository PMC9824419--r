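#' @importFrom rlang abort warn .data %||%
#' @importFrom stats sd var predict approx
#' @importFrom utils read.csv write.csv
NULL

# classed condition helper: all leafcal errors carry class "leafcal_error"
# plus a specific subclass so callers/tests can dispatch on failure mode.
lc_abort <- function(message, class) {
  rlang::abort(message, class = c(paste0("leafcal_", class), "leafcal_error"))
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# run code with a temporary RNG seed, restoring global state afterwards;
# seed = NULL runs with the current stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# 2D moving-window (box) sum with window half-width r; zero-padded edges.
# Used for the local-plane moment sums in estimate_normals().
boxsum2d <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0, nr + 2L * r, nc + 2L * r)
  p[(r + 1L):(r + nr), (r + 1L):(r + nc)] <- m
  cs <- apply(apply(p, 2L, cumsum), 1L, cumsum) # transposed integral image
  cs <- t(cs)
  z <- matrix(0, nrow(cs) + 1L, ncol(cs) + 1L)
  z[-1L, -1L] <- cs
  w <- 2L * r + 1L
  i0 <- (r + 1L):(r + nr); j0 <- (r + 1L):(r + nc)
  z[i0 + r + 1L, j0 + r + 1L, drop = FALSE] -
    z[i0 - r, j0 + r + 1L, drop = FALSE] -
    z[i0 + r + 1L, j0 - r, drop = FALSE] +
    z[i0 - r, j0 - r, drop = FALSE]
}

trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
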