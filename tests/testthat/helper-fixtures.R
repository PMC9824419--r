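# small in-code fixtures shared across test files

# uniform reflectance cube on the generator's 5-band axis
flat_cube <- function(rows = 4L, cols = 4L,
                      refl = c(0.10, 0.05, 0.35, 0.55, 0.52),
                      kind = "reflectance") {
  a <- array(rep(refl, each = rows * cols), c(rows, cols, length(refl)))
  hsi_cube(a, c(560, 680, 732, 800, 900), kind = kind)
}

# plane point cloud tilted `theta` deg toward azimuth `alpha`
plane_cloud <- function(theta, alpha, n = 41L, pitch = 0.001, sigma_z = 0) {
  g <- (seq_len(n) - (n + 1) / 2) * pitch
  X <- matrix(rep(g, n), n, n)
  Y <- matrix(rep(g, each = n), n, n)
  gr <- -tan(theta * pi / 180) * c(cos(alpha * pi / 180),
                                   sin(alpha * pi / 180))
  Z <- gr[1] * X + gr[2] * Y
  if (sigma_z > 0) Z <- Z + matrix(rnorm(n * n, 0, sigma_z), n, n)
  point_cloud(X, Y, Z)
}

# interior (eroded) mask: TRUE where the full window around a pixel is TRUE
erode_mask <- function(mask, r) {
  leafcal:::boxsum2d(mask * 1, r) == (2 * r + 1)^2 & mask
}

# brute-force balanced two-way ANOVA sums of squares from cell means
anova_oracle <- function(y, A, B) {
  A <- factor(A); B <- factor(B)
  a <- nlevels(A); b <- nlevels(B); r <- length(y) / (a * b)
  grand <- mean(y)
  mA <- tapply(y, A, mean); mB <- tapply(y, B, mean)
  mAB <- tapply(y, list(A, B), mean)
  ssa <- b * r * sum((mA - grand)^2)
  ssb <- a * r * sum((mB - grand)^2)
  ssab <- r * sum((sweep(sweep(mAB, 1, mA), 2, mB) + grand)^2)
  sse <- sum((y - mAB[cbind(A, B)])^2)
  c(Columns = ssa, Rows = ssb, Interaction = ssab, Error = sse,
    Total = sum((y - grand)^2))
}
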