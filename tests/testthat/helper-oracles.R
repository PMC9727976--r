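# Independent oracles and small fixture builders used across the suite.

# dense 2-D convolution with a unit-sum Gaussian truncated at 3 sigma and
# symmetric (edge-included) reflection -- the brute-force counterpart of the
# package's separable surround filter
dense_gauss_blur <- function(x, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k1 <- exp(-0.5 * (-r:r)^2 / sigma^2)
  k2 <- outer(k1, k1); k2 <- k2 / sum(k2)
  H <- nrow(x); W <- ncol(x)
  refl <- function(i, n) {
    while (any(i < 1 | i > n)) {
      i <- ifelse(i < 1, 1 - i, i)
      i <- ifelse(i > n, 2 * n + 1 - i, i)
    }
    i
  }
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- 0
    for (di in -r:r) for (dj in -r:r)
      acc <- acc + k2[di + r + 1, dj + r + 1] * x[refl(i + di, H), refl(j + dj, W)]
    out[i, j] <- acc
  }
  out
}

# high-resolution ray marching: same outermost-crossing definition as
# radial_boundary but with an arbitrarily fine step
ray_march_fine <- function(mask, structure, center, n_dirs = 24, step = 0.005) {
  pos <- if (structure == "OD") mask >= 1 else mask == 2
  H <- nrow(mask); W <- ncol(mask)
  th <- 2 * pi * (seq_len(n_dirs) - 1) / n_dirs
  tt <- seq(0, sqrt(H^2 + W^2), by = step)
  vapply(th, function(a) {
    xi <- round(center[1] + tt * cos(a)); yi <- round(center[2] + tt * sin(a))
    ok <- xi >= 1 & xi <= W & yi >= 1 & yi <= H
    hit <- ok & pos[pmin(pmax(yi, 1), H) + (pmin(pmax(xi, 1), W) - 1) * H]
    if (any(hit)) tt[max(which(hit))] else 0
  }, numeric(1))
}

# filled-circle / concentric disc-cup masks
circle_mask <- function(size, center, radius, label = 1L) {
  x <- matrix(rep(seq_len(size), each = size), size, size)
  y <- matrix(rep(seq_len(size), size), size, size)
  m <- matrix(0L, size, size)
  m[sqrt((x - center[1])^2 + (y - center[2])^2) <= radius] <- label
  m
}

disc_cup_mask <- function(size, center, r_disc, r_cup) {
  m <- circle_mask(size, center, r_disc, 1L)
  m[circle_mask(size, center, r_cup, 1L) == 1L] <- 2L
  m
}

# irregular blob mask from thresholded smoothed noise (seeded)
blob_mask <- function(size = 64, seed = 1, thr = 0.55) {
  set.seed(seed)
  sm <- fundusseg:::cpp_gauss_blur(matrix(runif(size * size), size, size), 6)
  m <- matrix(0L, size, size)
  m[sm > quantile(sm, thr)] <- 1L
  m
}

# radial gradient test image on a 101 x 101 canvas
radial_gradient_image <- function(size = 101, radius = 50) {
  c0 <- (size + 1) / 2
  x <- matrix(rep(seq_len(size), each = size), size, size)
  y <- matrix(rep(seq_len(size), size), size, size)
  r <- sqrt((x - c0)^2 + (y - c0)^2)
  list(img = matrix(pmin(255, r / radius * 255), size, size), r = r, center = c(c0, c0))
}

# synthetic high-contrast disc fixture for the Retinex contrast check
disc_fixture <- function(size = 32, radius = 10, lo = 30, hi = 200) {
  c0 <- (size + 1) / 2
  x <- matrix(rep(seq_len(size), each = size), size, size)
  y <- matrix(rep(seq_len(size), size), size, size)
  cc <- sqrt((x - c0)^2 + (y - c0)^2)
  img <- array(lo, c(size, size, 3))
  for (ch in 1:3) { p <- img[, , ch]; p[cc <= radius] <- hi; img[, , ch] <- p }
  list(img = img, cc = cc, radius = radius)
}

# mean gradient magnitude of the luminance over the boundary ring
ring_contrast <- function(img, cc, radius, width = 1.5) {
  lum <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  n <- nrow(lum)
  gx <- cbind(lum[, -1] - lum[, -n], 0)
  gy <- rbind(lum[-1, ] - lum[-n, ], 0)
  gm <- sqrt(gx^2 + gy^2)
  mean(gm[abs(cc - radius) <= width])
}
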