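# Cartesian <-> polar warping about the optic-disc centre. The polar image
# stacks radii along rows and angles along columns, which turns the nested
# disc/cup geometry into horizontal bands and rebalances class proportions.
# Convention: x = column index (rightward), y = row index (downward), both
# 1-based; theta is measured from the +x axis increasing clockwise on screen,
# theta in [0, 2*pi).

#' Polar sampling grid
#'
#' Describes the (radius, angle) geometry linking Cartesian and polar
#' representations. Angle samples are `theta_j = 2*pi*j/n_angles` for
#' `j = 0..n_angles-1`; radius samples are `r_i = max_radius*i/(n_radii-1)`
#' for `i = 0..n_radii-1`.
#'
#' @param center `c(cx, cy)` centre in image pixel coordinates (x = column,
#'   y = row, 1-based).
#' @param max_radius Largest sampled radius in pixels, positive.
#' @param n_radii Number of radius samples (rows of the polar image), >= 2.
#' @param n_angles Number of angle samples (columns), >= 4.
#' @return An object of class `polar_grid`.
#' @export
polar_grid <- function(center, max_radius, n_radii = 512, n_angles = 512) {
  if (length(center) != 2 || !is.numeric(center)) stop("center must be c(cx, cy)")
  if (max_radius <= 0) stop("max_radius must be positive")
  if (n_radii < 2 || n_angles < 4) stop("need n_radii >= 2 and n_angles >= 4")
  structure(list(center = as.numeric(center), max_radius = as.numeric(max_radius),
                 n_radii = as.integer(n_radii), n_angles = as.integer(n_angles)),
            class = "polar_grid")
}

polar_angles <- function(grid) 2 * pi * (seq_len(grid$n_angles) - 1) / grid$n_angles
polar_radii <- function(grid) grid$max_radius * (seq_len(grid$n_radii) - 1) / (grid$n_radii - 1)

#' Warp an image to polar coordinates
#'
#' `out[i, j, ]` samples the source at
#' `(cx + r_i*cos(theta_j), cy + r_i*sin(theta_j))`. Samples falling outside
#' the image take the fill value 0. Label masks must use nearest
#' interpolation so labels stay in `{0, 1, 2}`.
#'
#' @param image H x W or H x W x C numeric array.
#' @param grid A [polar_grid()]; its centre must lie inside the image.
#' @param interpolation `"bilinear"` (intensities) or `"nearest"` (labels).
#' @return `n_radii x n_angles (x C)` array.
#' @export
to_polar <- function(image, grid, interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  was_mat <- is.matrix(image)
  image <- as_image_array(image)
  H <- dim(image)[1]; W <- dim(image)[2]
  cx <- grid$center[1]; cy <- grid$center[2]
  if (cx < 1 || cx > W || cy < 1 || cy > H) stop("polar centre lies outside the image")
  th <- polar_angles(grid); r <- polar_radii(grid)
  xq <- cx + outer(r, cos(th))
  yq <- cy + outer(r, sin(th))
  fun <- if (interpolation == "bilinear") sample_bilinear else sample_nearest
  v <- fun(image, as.vector(xq), as.vector(yq), fill = 0)
  out <- array(v, dim = c(grid$n_radii, grid$n_angles, dim(image)[3]))
  if (was_mat) out[, , 1] else out
}

#' Warp a polar image back to Cartesian coordinates
#'
#' For each Cartesian pixel within `max_radius` of the centre, samples the
#' polar image at radius `sqrt((x-cx)^2 + (y-cy)^2)` and angle
#' `theta = atan2(y-cy, x-cx)` mapped to `[0, 2*pi)` (with angular
#' wrap-around for bilinear interpolation). Pixels beyond `max_radius` take
#' the fill value 0 (background label for masks).
#'
#' @param polar_image `n_radii x n_angles (x C)` array matching `grid`.
#' @param grid The [polar_grid()] used to produce `polar_image`.
#' @param out_shape `c(H, W)` of the Cartesian output.
#' @param interpolation `"bilinear"` or `"nearest"`.
#' @return `H x W (x C)` array.
#' @export
from_polar <- function(polar_image, grid, out_shape,
                       interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  was_mat <- is.matrix(polar_image)
  polar_image <- as_image_array(polar_image)
  if (dim(polar_image)[1] != grid$n_radii || dim(polar_image)[2] != grid$n_angles)
    stop("polar image dimensions do not match the grid")
  H <- out_shape[1]; W <- out_shape[2]; C <- dim(polar_image)[3]
  cx <- grid$center[1]; cy <- grid$center[2]
  x <- matrix(rep(seq_len(W), each = H), H, W) - cx
  y <- matrix(rep(seq_len(H), W), H, W) - cy
  r <- sqrt(x^2 + y^2)
  th <- atan2(y, x) %% (2 * pi)
  inside <- r <= grid$max_radius
  # fractional polar indices (1-based)
  iq <- 1 + r / grid$max_radius * (grid$n_radii - 1)
  jq <- 1 + th / (2 * pi) * grid$n_angles
  out <- array(0, dim = c(H, W, C))
  idx <- which(inside)
  if (length(idx) > 0) {
    if (interpolation == "nearest") {
      ii <- pmin(pmax(round(iq[idx]), 1L), grid$n_radii)
      jj <- round(jq[idx])
      jj[jj > grid$n_angles] <- jj[jj > grid$n_angles] - grid$n_angles  # wrap
      jj <- pmin(pmax(jj, 1L), grid$n_angles)
      base <- ii + (jj - 1) * grid$n_radii
      for (c in seq_len(C))
        out[idx + (c - 1) * H * W] <- polar_image[base + (c - 1) * grid$n_radii * grid$n_angles]
    } else {
      # pad one wrapped column so bilinear interpolation crosses theta = 0
      padded <- polar_image[, c(seq_len(grid$n_angles), 1L), , drop = FALSE]
      v <- sample_bilinear(padded, jq[idx], iq[idx], fill = 0)
      for (c in seq_len(C)) out[idx + (c - 1) * H * W] <- v[, c]
    }
  }
  if (was_mat) out[, , 1] else out
}

#' Disc centroid of a label mask
#'
#' Centroid `c(cx, cy)` of the disc region (labels `{1, 2}`), the default
#' centre for polar warping and BLE rays.
#'
#' @param mask Label matrix over `{0, 1, 2}` containing disc pixels.
#' @return Numeric `c(cx, cy)` in pixel coordinates.
#' @export
disc_centroid <- function(mask) {
  idx <- which(mask >= 1, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("mask contains no disc pixels")
  c(mean(idx[, 2]), mean(idx[, 1]))  # (cx, cy) = (col, row)
}

# largest radius about (cx, cy) fully inside an H x W image
max_inscribed_radius <- function(center, h, w) {
  min(center[1] - 1, w - center[1], center[2] - 1, h - center[2])
}
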