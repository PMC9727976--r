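# Synthetic fundus generator. Emulates the structure of disc-centred fundus
# photographs: a reddish vascularised background with a smooth illumination
# gradient, dark curved vessel strokes, a bright elliptical optic disc with
# a Gaussian-blurred rim and a smaller, brighter, blurrier optic cup strictly
# inside the disc. The ground-truth mask comes from the analytic ellipse
# geometry, so the vertical cup-to-disc ratio is controlled by construction.

#' Parameters of the synthetic fundus generator
#'
#' @param image_size Side length in pixels.
#' @param disc_radius_range Interval for the disc's vertical semi-axis, px;
#'   defaults to 20--31% of the image side.
#' @param cdr_range Interval in (0, 1) for the vertical cup-to-disc ratio.
#' @param disc_eccentricity_range Interval for the horizontal/vertical
#'   semi-axis ratio of disc and cup.
#' @param vessel_count_range Integer interval for the number of vessel
#'   strokes.
#' @param illumination_gradient_strength Peak-to-peak amplitude of the
#'   linear illumination ramp, intensity units.
#' @param noise_sigma Standard deviation of pixel noise, intensity units.
#' @param blur_sigma_disc,blur_sigma_cup Rim blur of disc and cup, px. The
#'   cup rim is blurrier, mirroring the weak cup boundary in real fundus
#'   images.
#' @param seed Integer seed; generation is a deterministic function of it.
#' @return A `synthetic_fundus_params` object.
#' @export
synthetic_fundus_params <- function(image_size = 128,
                                    disc_radius_range = round(image_size * c(0.20, 0.31)),
                                    cdr_range = c(0.3, 0.8),
                                    disc_eccentricity_range = c(0.85, 1.15),
                                    vessel_count_range = c(2, 8),
                                    illumination_gradient_strength = 40,
                                    noise_sigma = 6,
                                    blur_sigma_disc = 2,
                                    blur_sigma_cup = 3.5,
                                    seed = 1) {
  if (cdr_range[1] <= 0 || cdr_range[2] >= 1 || cdr_range[1] > cdr_range[2])
    stop("cdr_range must lie strictly inside (0, 1)")
  if (max(disc_radius_range) * max(disc_eccentricity_range) > image_size / 2 - 4)
    stop("disc does not fit inside the image")
  structure(list(image_size = as.integer(image_size),
                 disc_radius_range = disc_radius_range, cdr_range = cdr_range,
                 disc_eccentricity_range = disc_eccentricity_range,
                 vessel_count_range = as.integer(vessel_count_range),
                 illumination_gradient_strength = illumination_gradient_strength,
                 noise_sigma = noise_sigma, blur_sigma_disc = blur_sigma_disc,
                 blur_sigma_cup = blur_sigma_cup, seed = as.integer(seed)),
            class = "synthetic_fundus_params")
}

# soft-edged ellipse membership in [0,1]: 1 inside, 0 outside, blurred rim
soft_ellipse <- function(H, W, cx, cy, a, b, blur_sigma) {
  x <- matrix(rep(seq_len(W), each = H), H, W)
  y <- matrix(rep(seq_len(H), W), H, W)
  inside <- ((x - cx) / a)^2 + ((y - cy) / b)^2 <= 1
  m <- matrix(as.numeric(inside), H, W)
  if (blur_sigma > 0) m <- cpp_gauss_blur(m, blur_sigma)
  m
}

hard_ellipse <- function(H, W, cx, cy, a, b) {
  x <- matrix(rep(seq_len(W), each = H), H, W)
  y <- matrix(rep(seq_len(H), W), H, W)
  ((x - cx) / a)^2 + ((y - cy) / b)^2 <= 1
}

#' Generate one synthetic fundus image with ground truth
#'
#' Deterministic in `params$seed` (plus the `seed` offset argument). The
#' returned mask uses labels 0 (background), 1 (disc) and 2 (cup), with the
#' cup a strict subset of the disc; the measured [vertical_cdr()] of the
#' mask matches the sampled target CDR to within about 0.02 (rasterisation
#' granularity).
#'
#' @param params A [synthetic_fundus_params()] object.
#' @param seed Optional seed overriding `params$seed`.
#' @return List with `image` (`H x W x 3`, 0..255), `mask` (`H x W` labels)
#'   and `center` (`c(cx, cy)` disc centroid).
#' @export
generate_synthetic_fundus <- function(params = synthetic_fundus_params(), seed = NULL) {
  stopifnot(inherits(params, "synthetic_fundus_params"))
  seed <- seed %||% params$seed
  with_seed(seed, {
    S <- params$image_size
    H <- S; W <- S
    # disc geometry: vertical semi-axis b, horizontal a = b * eccentricity
    b_disc <- runif(1, params$disc_radius_range[1], params$disc_radius_range[2])
    ecc <- runif(1, params$disc_eccentricity_range[1], params$disc_eccentricity_range[2])
    a_disc <- b_disc * ecc
    margin_x <- a_disc + 6; margin_y <- b_disc + 6
    cx <- runif(1, margin_x + 1, W - margin_x)
    cy <- runif(1, margin_y + 1, H - margin_y)
    target_cdr <- runif(1, params$cdr_range[1], params$cdr_range[2])

    disc_in <- hard_ellipse(H, W, cx, cy, a_disc, b_disc)
    disc_rows <- which(apply(disc_in, 1, any))
    vdd <- max(disc_rows) - min(disc_rows) + 1
    # choose the cup's vertical semi-axis so the rasterised vertical extents
    # realise the target CDR: find the half-height whose row count at the
    # cup centre equals round(cdr * VDD), taking the middle of the matching
    # interval so sub-pixel effects cannot flip the count
    vcd_target <- max(3L, round(target_cdr * vdd))
    hs <- seq(max(vcd_target / 2 - 1.5, 1), vcd_target / 2 + 1.5, by = 0.01)
    cnt <- floor(cy + hs) - ceiling(cy - hs) + 1
    match_h <- hs[cnt == vcd_target]
    b_cup <- if (length(match_h) > 0) mean(range(match_h)) else vcd_target / 2
    b_cup <- min(b_cup, b_disc - 2)
    a_cup <- min(b_cup * ecc, a_disc - 3)
    # small centre jitter, kept so the cup stays strictly inside the disc
    jx <- runif(1, -1, 1) * max(a_disc - a_cup - 3, 0) * 0.3
    jy <- 0  # vertical jitter would disturb the vertical CDR
    cup_in <- hard_ellipse(H, W, cx + jx, cy + jy, a_cup, b_cup)
    cup_in <- cup_in & disc_in

    mask <- matrix(0L, H, W)
    mask[disc_in] <- 1L
    mask[cup_in] <- 2L

    # ---- render the image ----
    base <- c(175, 78, 52)  # reddish fundus background
    grad_dir <- runif(1, 0, 2 * pi)
    gx <- matrix(rep(seq_len(W), each = H), H, W) / W - 0.5
    gy <- matrix(rep(seq_len(H), W), H, W) / H - 0.5
    ramp <- (gx * cos(grad_dir) + gy * sin(grad_dir)) *
      params$illumination_gradient_strength
    texture <- cpp_gauss_blur(matrix(rnorm(H * W, sd = 25), H, W), 4)

    # vessels: dark quadratic strokes through the field
    n_ves <- sample(params$vessel_count_range[1]:params$vessel_count_range[2], 1)
    vessel <- matrix(0, H, W)
    for (v in seq_len(n_ves)) {
      p0 <- c(runif(1, 1, W), runif(1, 1, H))
      p2 <- c(runif(1, 1, W), runif(1, 1, H))
      p1 <- (p0 + p2) / 2 + rnorm(2, sd = S / 5)
      tseq <- seq(0, 1, length.out = 4 * S)
      bx <- (1 - tseq)^2 * p0[1] + 2 * tseq * (1 - tseq) * p1[1] + tseq^2 * p2[1]
      by <- (1 - tseq)^2 * p0[2] + 2 * tseq * (1 - tseq) * p1[2] + tseq^2 * p2[2]
      xi <- round(bx); yi <- round(by)
      ok <- xi >= 1 & xi <= W & yi >= 1 & yi <= H
      vessel[cbind(yi[ok], xi[ok])] <- 1
    }
    vessel <- pmin(cpp_gauss_blur(vessel, 0.8) * 2.5, 1)

    disc_soft <- soft_ellipse(H, W, cx, cy, a_disc, b_disc, params$blur_sigma_disc)
    cup_soft <- soft_ellipse(H, W, cx + jx, cy + jy, a_cup, b_cup, params$blur_sigma_cup)

    disc_col <- c(238, 190, 90)   # bright yellowish disc
    cup_col <- c(252, 226, 140)   # brighter, paler cup
    img <- array(0, dim = c(H, W, 3))
    for (ch in 1:3) {
      plane <- base[ch] + ramp + texture * 0.4
      plane <- plane * (1 - 0.55 * vessel)  # dark vessels
      plane <- plane * (1 - disc_soft) + disc_col[ch] * disc_soft
      plane <- plane * (1 - cup_soft) + cup_col[ch] * cup_soft
      plane <- plane + matrix(rnorm(H * W, sd = params$noise_sigma), H, W)
      img[, , ch] <- pmin(pmax(plane, 0), 255)
    }
    list(image = img, mask = mask, center = disc_centroid(mask))
  })
}

#' Generate a synthetic dataset
#'
#' Draws `n` images with seeds `seed + 0 .. seed + n - 1` and optionally
#' writes them to `dir` in the standard layout (`images/*.png`,
#' `masks/*.png` with matching stems).
#'
#' @param n Number of images.
#' @param params A [synthetic_fundus_params()].
#' @param seed Base seed.
#' @param dir Optional output directory.
#' @return Invisibly, a list of `generate_synthetic_fundus()` results.
#' @export
generate_synthetic_dataset <- function(n, params = synthetic_fundus_params(),
                                       seed = 1, dir = NULL) {
  out <- lapply(seq_len(n) - 1L, function(k) generate_synthetic_fundus(params, seed = seed + k))
  if (!is.null(dir)) {
    dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
    for (k in seq_len(n)) {
      stem <- sprintf("synthetic_%04d", k)
      write_fundus(out[[k]]$image, file.path(dir, "images", paste0(stem, ".png")))
      write_mask(out[[k]]$mask, file.path(dir, "masks", paste0(stem, ".png")))
    }
  }
  invisible(out)
}
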