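# Data augmentation: multi-size crops centred on the disc, random flips,
# free-angle rotation, and a resize to the network input size. Identical
# geometric transforms are applied to image (bilinear) and mask (nearest) so
# labels stay in {0, 1, 2}.

#' Augmentation settings
#'
#' @param crop_sizes Candidate square crop side lengths in source pixels;
#'   one is drawn per augmentation. Crops larger than the source are
#'   zero-padded.
#' @param hflip,vflip Probabilities of horizontal / vertical flips.
#' @param rotation_range Rotation interval in degrees within `[0, 360]`.
#' @param output_size Side length after the final resize.
#' @return An `augmentation_spec` object.
#' @export
augmentation_spec <- function(crop_sizes = seq(400, 900, by = 50),
                              hflip = 0.5, vflip = 0.5,
                              rotation_range = c(0, 360), output_size = 512) {
  if (any(crop_sizes <= 0)) stop("crop sizes must be positive")
  if (rotation_range[1] < 0 || rotation_range[2] > 360 ||
      rotation_range[1] > rotation_range[2]) stop("rotation range must lie within [0, 360]")
  structure(list(crop_sizes = as.integer(crop_sizes), hflip = hflip, vflip = vflip,
                 rotation_range = rotation_range, output_size = as.integer(output_size)),
            class = "augmentation_spec")
}

# crop a square window of side `size` centred at (cx, cy); zero-pad outside
crop_centered <- function(img, cx, cy, size) {
  was_mat <- is.matrix(img)
  img <- as_image_array(img)
  H <- dim(img)[1]; W <- dim(img)[2]; C <- dim(img)[3]
  x0 <- round(cx) - size %/% 2; y0 <- round(cy) - size %/% 2
  out <- array(0, dim = c(size, size, C))
  xs <- x0:(x0 + size - 1); ys <- y0:(y0 + size - 1)
  okx <- xs >= 1 & xs <= W; oky <- ys >= 1 & ys <= H
  out[which(oky), which(okx), ] <- img[ys[oky], xs[okx], , drop = FALSE]
  if (was_mat) out[, , 1] else out
}

# rotate about the image centre by `deg` degrees (clockwise on screen),
# inverse-mapping with the requested interpolation
rotate_image <- function(img, deg, interpolation = "bilinear", fill = 0) {
  was_mat <- is.matrix(img)
  img <- as_image_array(img)
  H <- dim(img)[1]; W <- dim(img)[2]
  cx <- (W + 1) / 2; cy <- (H + 1) / 2
  th <- deg * pi / 180
  x <- matrix(rep(seq_len(W), each = H), H, W) - cx
  y <- matrix(rep(seq_len(H), W), H, W) - cy
  xq <- cx + cos(th) * x + sin(th) * y
  yq <- cy - sin(th) * x + cos(th) * y
  fun <- if (interpolation == "bilinear") sample_bilinear else sample_nearest
  v <- fun(img, as.vector(xq), as.vector(yq), fill = fill)
  out <- array(v, dim = dim(img))
  if (was_mat) out[, , 1] else out
}

#' Augment an image/mask pair
#'
#' Samples one crop size, crops centred on the disc centroid of the mask,
#' applies flips and a rotation drawn from the spec, and resizes to
#' `spec$output_size`. The image is interpolated bilinearly and the mask
#' with nearest-neighbour sampling.
#'
#' @param image `H x W x 3` array.
#' @param mask `H x W` label matrix over `{0, 1, 2}` containing disc pixels.
#' @param spec An [augmentation_spec()].
#' @param seed Seed making the augmentation reproducible.
#' @return List with `image` and `mask`.
#' @export
augment <- function(image, mask, spec = augmentation_spec(), seed = 1) {
  if (!any(mask >= 1)) stop("mask contains no disc pixels; cannot centre the crop")
  check_mask(mask)
  with_seed(seed, {
    ctr <- disc_centroid(mask)
    size <- if (length(spec$crop_sizes) == 1) spec$crop_sizes else sample(spec$crop_sizes, 1)
    img <- crop_centered(image, ctr[1], ctr[2], size)
    msk <- crop_centered(mask, ctr[1], ctr[2], size)
    if (runif(1) < spec$hflip) { img <- img[, rev(seq_len(dim(img)[2])), , drop = FALSE]; msk <- msk[, rev(seq_len(ncol(msk)))] }
    if (runif(1) < spec$vflip) { img <- img[rev(seq_len(dim(img)[1])), , , drop = FALSE]; msk <- msk[rev(seq_len(nrow(msk))), ] }
    deg <- runif(1, spec$rotation_range[1], spec$rotation_range[2])
    if (deg != 0) {
      img <- rotate_image(img, deg, "bilinear")
      msk <- rotate_image(msk, deg, "nearest")
    }
    so <- spec$output_size
    list(image = resize_bilinear(img, so, so),
         mask = matrix(as.integer(resize_nearest(msk, so, so)), so, so))
  })
}
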