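# Shared resampling helpers. Coordinates follow the image-raster convention
# used throughout the package: x = column index increasing rightward,
# y = row index increasing downward, both 1-based at pixel centres.

# ensure an image is H x W x C (promote a matrix to one channel)
as_image_array <- function(img) {
  if (is.matrix(img)) img <- array(img, dim = c(dim(img), 1L))
  if (length(dim(img)) != 3L) stop("image must be an H x W or H x W x C array")
  img
}

# gather samples at continuous (xq, yq); returns length(xq) x C matrix
sample_nearest <- function(img, xq, yq, fill = 0) {
  img <- as_image_array(img)
  H <- dim(img)[1]; W <- dim(img)[2]; C <- dim(img)[3]
  xi <- round(xq); yi <- round(yq)
  ok <- xi >= 1 & xi <= W & yi >= 1 & yi <= H
  out <- matrix(fill, nrow = length(xq), ncol = C)
  if (any(ok)) {
    base <- (yi[ok]) + (xi[ok] - 1) * H
    for (c in seq_len(C)) out[ok, c] <- img[base + (c - 1) * H * W]
  }
  out
}

sample_bilinear <- function(img, xq, yq, fill = 0) {
  img <- as_image_array(img)
  H <- dim(img)[1]; W <- dim(img)[2]; C <- dim(img)[3]
  ok <- xq >= 1 & xq <= W & yq >= 1 & yq <= H
  out <- matrix(fill, nrow = length(xq), ncol = C)
  if (any(ok)) {
    x <- pmin(pmax(xq[ok], 1), W); y <- pmin(pmax(yq[ok], 1), H)
    x0 <- pmin(floor(x), W - 1L); y0 <- pmin(floor(y), H - 1L)
    if (W == 1L) x0 <- rep(1, length(x))
    if (H == 1L) y0 <- rep(1, length(y))
    x1 <- pmin(x0 + 1L, W); y1 <- pmin(y0 + 1L, H)
    wx <- x - x0; wy <- y - y0
    i00 <- y0 + (x0 - 1) * H; i10 <- y1 + (x0 - 1) * H
    i01 <- y0 + (x1 - 1) * H; i11 <- y1 + (x1 - 1) * H
    for (c in seq_len(C)) {
      off <- (c - 1) * H * W
      v <- (1 - wx) * ((1 - wy) * img[i00 + off] + wy * img[i10 + off]) +
        wx * ((1 - wy) * img[i01 + off] + wy * img[i11 + off])
      out[ok, c] <- v
    }
  }
  out
}

# 1-D linear interpolation matrix (n_out x n_in), endpoints aligned
linear_interp_matrix <- function(n_in, n_out) {
  M <- matrix(0, n_out, n_in)
  if (n_in == 1L) { M[, 1] <- 1; return(M) }
  pos <- if (n_out == 1L) (n_in + 1) / 2 else 1 + (seq_len(n_out) - 1) * (n_in - 1) / (n_out - 1)
  i0 <- pmin(floor(pos), n_in - 1L)
  w <- pos - i0
  M[cbind(seq_len(n_out), i0)] <- M[cbind(seq_len(n_out), i0)] + (1 - w)
  M[cbind(seq_len(n_out), i0 + 1L)] <- M[cbind(seq_len(n_out), i0 + 1L)] + w
  M
}

# separable bilinear resize of an H x W (x C) array
resize_bilinear <- function(img, h_out, w_out) {
  was_mat <- is.matrix(img)
  img <- as_image_array(img)
  Lh <- linear_interp_matrix(dim(img)[1], h_out)
  Lw <- linear_interp_matrix(dim(img)[2], w_out)
  out <- array(0, dim = c(h_out, w_out, dim(img)[3]))
  for (c in seq_len(dim(img)[3])) out[, , c] <- Lh %*% img[, , c] %*% t(Lw)
  if (was_mat) out[, , 1] else out
}

resize_nearest <- function(img, h_out, w_out) {
  was_mat <- is.matrix(img)
  img <- as_image_array(img)
  H <- dim(img)[1]; W <- dim(img)[2]
  ri <- if (h_out == 1L) round((H + 1) / 2) else round(1 + (seq_len(h_out) - 1) * (H - 1) / (h_out - 1))
  ci <- if (w_out == 1L) round((W + 1) / 2) else round(1 + (seq_len(w_out) - 1) * (W - 1) / (w_out - 1))
  out <- img[ri, ci, , drop = FALSE]
  if (was_mat) out[, , 1] else out
}
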