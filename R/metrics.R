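# Segmentation evaluation: confusion-based rates, F1, the radial boundary
# localization error (BLE) and the vertical cup-to-disc ratio (CDR).
# Masks are integer matrices over {0 background, 1 optic disc, 2 optic cup};
# the OD positive class includes cup pixels because the cup is anatomically
# part of the disc region.

check_mask <- function(mask, name = "mask") {
  if (!is.matrix(mask)) stop(name, " must be a matrix")
  bad <- setdiff(unique(as.vector(mask)), c(0, 1, 2))
  if (length(bad) > 0)
    stop(name, " contains labels outside {0,1,2}: ", paste(bad, collapse = ", "))
  invisible(mask)
}

structure_positive <- function(mask, structure = c("OD", "OC")) {
  structure <- match.arg(structure)
  if (structure == "OD") mask >= 1 else mask == 2
}

#' Pixel-wise confusion counts for one structure
#'
#' Binarises prediction and ground truth for the requested structure and
#' tallies TP/FP/TN/FN. For the optic disc (`"OD"`) the positive class is
#' labels `{1, 2}` (the cup lies inside the disc); for the optic cup
#' (`"OC"`) it is label `{2}`.
#'
#' @param pred_mask,gt_mask Same-shape matrices with labels in `{0, 1, 2}`.
#' @param structure `"OD"` or `"OC"`.
#' @return A `confusion_counts` object with fields TP, FP, TN, FN, P, N.
#' @export
confusion_counts <- function(pred_mask, gt_mask, structure = c("OD", "OC")) {
  if (!identical(dim(pred_mask), dim(gt_mask))) stop("mask shapes differ")
  check_mask(pred_mask, "pred_mask"); check_mask(gt_mask, "gt_mask")
  p <- structure_positive(pred_mask, structure)
  g <- structure_positive(gt_mask, structure)
  cc <- list(TP = sum(p & g), FP = sum(p & !g), TN = sum(!p & !g), FN = sum(!p & g))
  cc$P <- cc$TP + cc$FN
  cc$N <- cc$TN + cc$FP
  structure(cc, class = "confusion_counts")
}

#' F1 score (with precision and recall)
#'
#' `Precision = TP/(TP+FP)`, `Recall = TP/(TP+FN)`,
#' `F1 = 2*Precision*Recall/(Precision+Recall)`; any 0/0 is 0 by convention.
#'
#' @param c A [confusion_counts()] object.
#' @return Named list with `precision`, `recall`, `f1`.
#' @export
f1_score <- function(c) {
  safe_div <- function(a, b) if (b == 0) 0 else a / b
  precision <- safe_div(c$TP, c$TP + c$FP)
  recall <- safe_div(c$TP, c$TP + c$FN)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1)
}

#' Specificity, sensitivity and accuracy
#'
#' `SPC = TN/N`, `SEN = TP/P` and
#' `ACC = SPC*N/(P+N) + SEN*P/(P+N)`, which equals `(TP+TN)/(P+N)` exactly.
#' If P or N is zero the undefined rate is reported as `NA` and the result is
#' flagged degenerate.
#'
#' @param c A [confusion_counts()] object.
#' @return Named list with `spc`, `sen`, `acc`, `degenerate`.
#' @export
rate_metrics <- function(c) {
  degenerate <- c$P == 0 || c$N == 0
  spc <- if (c$N == 0) NA_real_ else c$TN / c$N
  sen <- if (c$P == 0) NA_real_ else c$TP / c$P
  tot <- c$P + c$N
  acc <- if (tot == 0) NA_real_ else
    (if (is.na(spc)) 0 else spc * c$N / tot) + (if (is.na(sen)) 0 else sen * c$P / tot)
  list(spc = spc, sen = sen, acc = acc, degenerate = degenerate)
}

#' Radial boundary of a structure
#'
#' Casts `n_dirs` equidistant rays from the centre (directions
#' `theta_k = 2*pi*k/n_dirs`) and records, per ray, the distance to the far
#' edge of the outermost pixel of the structure's positive class. Each ray
#' is traversed exactly, pixel cell by pixel cell (cells are unit squares
#' centred on pixel centres), up to the image border, so arbitrarily thin
#' corner clips are never skipped — the result agrees with fixed-step ray
#' marching in the limit of a vanishing step. Rays that hit no positive
#' pixel record distance 0; an entirely empty structure is flagged.
#'
#' @param mask Label matrix over `{0, 1, 2}`.
#' @param structure `"OD"` or `"OC"`.
#' @param center `c(cx, cy)` in pixel coordinates, inside the mask.
#' @param n_dirs Number of directions (default 24).
#' @return A `radial_boundary` object: `center`, `distances` (length
#'   `n_dirs`), `empty` flag.
#' @export
radial_boundary <- function(mask, structure = c("OD", "OC"), center,
                            n_dirs = 24) {
  check_mask(mask)
  H <- nrow(mask); W <- ncol(mask)
  cx <- center[1]; cy <- center[2]
  if (cx < 1 || cx > W || cy < 1 || cy > H) stop("center outside mask bounds")
  pos <- structure_positive(mask, structure)
  empty <- !any(pos)
  th <- 2 * pi * (seq_len(n_dirs) - 1) / n_dirs
  distances <- vapply(th, function(a) {
    dx <- cos(a); dy <- sin(a)
    # exit time from the image (cells span [k - 0.5, k + 0.5))
    tx <- if (abs(dx) > 1e-12) ((if (dx > 0) W + 0.5 else 0.5) - cx) / dx else Inf
    ty <- if (abs(dy) > 1e-12) ((if (dy > 0) H + 0.5 else 0.5) - cy) / dy else Inf
    tmax <- min(tx, ty)
    # crossing times of all cell boundaries before tmax
    cross <- numeric(0)
    if (abs(dx) > 1e-12) {
      ks <- if (dx > 0) seq(floor(cx + 0.5), W) + 0.5 else seq(ceiling(cx - 0.5), 1) - 0.5
      cross <- c(cross, (ks - cx) / dx)
    }
    if (abs(dy) > 1e-12) {
      ks <- if (dy > 0) seq(floor(cy + 0.5), H) + 0.5 else seq(ceiling(cy - 0.5), 1) - 0.5
      cross <- c(cross, (ks - cy) / dy)
    }
    ts <- sort(unique(c(0, cross[cross > 0 & cross <= tmax], tmax)))
    if (length(ts) < 2) return(0)
    mid <- (ts[-1] + ts[-length(ts)]) / 2
    xi <- round(cx + mid * dx); yi <- round(cy + mid * dy)
    ok <- xi >= 1 & xi <= W & yi >= 1 & yi <= H
    hit <- ok & pos[pmin(pmax(yi, 1), H) + (pmin(pmax(xi, 1), W) - 1) * H]
    if (any(hit)) ts[max(which(hit)) + 1L] else 0
  }, numeric(1))
  if (empty) warning("structure is empty in mask; all boundary distances are 0")
  structure(list(center = as.numeric(center), distances = as.numeric(distances),
                 empty = empty), class = "radial_boundary")
}

#' Boundary localization error (BLE)
#'
#' Mean over `n_dirs` equidistant directions of the radial distance between
#' the ground-truth and predicted boundaries, both measured from the disc
#' centre: `BLE = mean(|d_g - d_0|)` in pixels. Lower is better and
#' `ble(m, m) = 0`. The form `"signed_sqrt"` evaluates
#' `sqrt(d_g^2 - d_0^2)` per direction instead and errors when the radicand
#' is negative; it is provided for comparison only since it is undefined
#' whenever the prediction overshoots the ground truth.
#'
#' If either mask lacks the structure the result is flagged degenerate and
#' equals `mean(|d_g|)` by convention (the full radial extent of whichever
#' boundary exists).
#'
#' @param pred,gt Label matrices over `{0, 1, 2}` of equal shape.
#' @param structure `"OD"` or `"OC"`.
#' @param center `c(cx, cy)` disc centre; defaults to the ground-truth disc
#'   centroid.
#' @param n_dirs Number of directions (default 24).
#' @param form `"absolute"` (default) or `"signed_sqrt"`.
#' @return BLE in pixels, with attribute `degenerate` when a structure was
#'   missing.
#' @export
ble <- function(pred, gt, structure = c("OD", "OC"), center = NULL,
                n_dirs = 24, form = c("absolute", "signed_sqrt")) {
  form <- match.arg(form)
  if (!identical(dim(pred), dim(gt))) stop("mask shapes differ")
  if (is.null(center)) center <- disc_centroid(gt)
  bg <- radial_boundary(gt, structure, center, n_dirs)
  suppressWarnings(bp <- radial_boundary(pred, structure, center, n_dirs))
  degenerate <- bg$empty || bp$empty
  if (form == "signed_sqrt") {
    rad <- bg$distances^2 - bp$distances^2
    if (any(rad < 0))
      stop("signed_sqrt BLE undefined: predicted boundary exceeds ground truth in some direction")
    val <- mean(sqrt(rad))
  } else {
    val <- mean(abs(bg$distances - bp$distances))
  }
  attr(val, "degenerate") <- degenerate
  val
}

#' Vertical cup-to-disc ratio
#'
#' Ratio of the vertical cup diameter (row extent of label 2) to the
#' vertical disc diameter (row extent of labels `{1, 2}`), using the
#' pixel-extent convention `max(row) - min(row) + 1`. A CDR above about 0.5
#' is the conventional glaucoma-risk threshold. Returns 0 when the cup is
#' absent and `NA` (with a warning) when the disc is absent.
#'
#' @param mask Label matrix over `{0, 1, 2}`.
#' @return The vertical CDR.
#' @export
vertical_cdr <- function(mask) {
  check_mask(mask)
  disc_rows <- which(apply(mask >= 1, 1, any))
  if (length(disc_rows) == 0) {
    warning("disc absent; vertical CDR undefined")
    return(NA_real_)
  }
  cup_rows <- which(apply(mask == 2, 1, any))
  if (length(cup_rows) == 0) return(0)
  vcd <- max(cup_rows) - min(cup_rows) + 1
  vdd <- max(disc_rows) - min(disc_rows) + 1
  vcd / vdd
}

#' Per-image segmentation metrics
#'
#' Computes, for one prediction/ground-truth pair, F1, accuracy, specificity
#' and sensitivity for disc and cup, the BLE of both boundaries and the
#' predicted and reference vertical CDR.
#'
#' @param pred,gt Label matrices over `{0, 1, 2}`.
#' @param center Disc centre for the BLE rays; defaults to the ground-truth
#'   disc centroid.
#' @param n_dirs BLE directions (default 24).
#' @return One-row `data.frame`.
#' @export
evaluate_masks <- function(pred, gt, center = NULL, n_dirs = 24) {
  if (is.null(center)) center <- disc_centroid(gt)
  row <- list()
  for (s in c("OD", "OC")) {
    cc <- confusion_counts(pred, gt, s)
    f <- f1_score(cc); r <- rate_metrics(cc)
    row[[paste0("F1_", s)]] <- f$f1
    row[[paste0("ACC_", s)]] <- r$acc
    row[[paste0("SPC_", s)]] <- r$spc
    row[[paste0("SEN_", s)]] <- r$sen
    row[[paste0("BLE_", s)]] <- as.numeric(ble(pred, gt, s, center, n_dirs))
  }
  row$CDR_pred <- suppressWarnings(vertical_cdr(pred))
  row$CDR_gt <- vertical_cdr(gt)
  as.data.frame(row)
}

#' Dataset-level metrics report
#'
#' Stacks [evaluate_masks()] rows for matched lists of predictions and
#' ground truths and appends the mean and standard deviation of every
#' column, matching the mean/std convention of segmentation benchmarks.
#'
#' @param preds,gts Lists of label matrices of equal length.
#' @param centers Optional list of disc centres.
#' @param n_dirs BLE directions.
#' @return A `metrics_report`: `per_image` data.frame and `summary`
#'   data.frame with rows `mean` and `sd`.
#' @export
metrics_report <- function(preds, gts, centers = NULL, n_dirs = 24) {
  stopifnot(length(preds) == length(gts))
  rows <- lapply(seq_along(preds), function(i) {
    ctr <- if (is.null(centers)) NULL else centers[[i]]
    evaluate_masks(preds[[i]], gts[[i]], ctr, n_dirs)
  })
  per_image <- do.call(rbind, rows)
  summary <- rbind(mean = colMeans(per_image, na.rm = TRUE),
                   sd = apply(per_image, 2, sd, na.rm = TRUE))
  structure(list(per_image = per_image, summary = as.data.frame(summary)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Segmentation metrics over", nrow(x$per_image), "images\n")
  print(round(x$summary, 4))
  invisible(x)
}
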