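test_that("confusion counts match pixel-by-pixel enumeration", {
  gt <- matrix(0L, 3, 3); gt[1, 1] <- 2L; gt[1, 2] <- 2L; gt[2, 1] <- 2L
  pred <- matrix(0L, 3, 3); pred[1, 1] <- 2L; pred[1, 2] <- 2L; pred[3, 3] <- 2L
  cc <- confusion_counts(pred, gt, "OC")
  expect_equal(cc$TP, 2); expect_equal(cc$FP, 1)
  expect_equal(cc$FN, 1); expect_equal(cc$TN, 5)
  expect_equal(cc$P + cc$N, 9)

  # exhaustive 2x2 case: gt all background, pred all cup
  cc2 <- confusion_counts(matrix(2L, 2, 2), matrix(0L, 2, 2), "OC")
  expect_equal(unlist(cc2[c("TP", "FP", "TN", "FN")]), c(TP = 0, FP = 4, TN = 0, FN = 0))

  # perfect prediction has no errors for either structure
  m <- disc_cup_mask(21, c(11, 11), 8, 4)
  for (s in c("OD", "OC")) {
    cp <- confusion_counts(m, m, s)
    expect_equal(cp$FP + cp$FN, 0)
  }
})

test_that("OD positive class includes cup pixels (nesting prior)", {
  gt <- matrix(0L, 4, 4); gt[2, 2] <- 1L; gt[2, 3] <- 2L
  pred <- matrix(0L, 4, 4); pred[2, 2] <- 2L; pred[2, 3] <- 1L
  cc <- confusion_counts(pred, gt, "OD")
  expect_equal(cc$TP, 2)  # label 1 vs 2 swaps do not matter for the disc
})

test_that("confusion counts reject malformed masks", {
  expect_error(confusion_counts(matrix(0L, 2, 2), matrix(0L, 3, 3)), "shapes")
  expect_error(confusion_counts(matrix(5L, 2, 2), matrix(0L, 2, 2)), "labels")
})

test_that("F1 follows the precision/recall arithmetic with 0/0 -> 0", {
  cc <- function(tp, fp, fn) structure(list(TP = tp, FP = fp, TN = 0, FN = fn,
                                            P = tp + fn, N = fp), class = "confusion_counts")
  expect_equal(f1_score(cc(4, 0, 0))$f1, 1)
  expect_equal(f1_score(cc(0, 3, 2))$f1, 0)
  r <- f1_score(cc(6, 2, 2))
  expect_equal(r$precision, 0.75); expect_equal(r$recall, 0.75); expect_equal(r$f1, 0.75)
  # symmetry in FP <-> FN
  expect_equal(f1_score(cc(5, 3, 1))$f1, f1_score(cc(5, 1, 3))$f1)
})

test_that("rate metrics satisfy the accuracy decomposition identity", {
  mk <- function(tp, fn, tn, fp) structure(list(TP = tp, FP = fp, TN = tn, FN = fn,
                                                P = tp + fn, N = tn + fp),
                                           class = "confusion_counts")
  r <- rate_metrics(mk(8, 2, 15, 5))
  expect_equal(r$spc, 0.75); expect_equal(r$sen, 0.8)
  expect_equal(r$acc, 23 / 30)
  expect_equal(rate_metrics(mk(10, 0, 20, 0)), list(spc = 1, sen = 1, acc = 1, degenerate = FALSE))
  expect_equal(rate_metrics(mk(0, 5, 0, 7))[1:3], list(spc = 0, sen = 0, acc = 0))
  # identity ACC = (TP+TN)/(P+N) over random tables
  set.seed(21)
  for (i in 1:50) {
    v <- sample(0:40, 4, replace = TRUE)
    m <- mk(v[1], v[2], v[3], v[4])
    r <- rate_metrics(m)
    if (!r$degenerate) expect_equal(r$acc, (m$TP + m$TN) / (m$P + m$N), tolerance = 1e-14)
  }
  # degenerate flagging
  expect_true(rate_metrics(mk(0, 0, 5, 5))$degenerate)
  expect_true(is.na(rate_metrics(mk(0, 0, 5, 5))$sen))
})

test_that("radial boundary recovers disc radii and flags empty structures", {
  m <- circle_mask(121, c(61, 61), 30)
  rb <- radial_boundary(m, "OD", c(61, 61), 24)
  # rasterised circle boundary: within a pixel of the analytic radius
  expect_true(all(abs(rb$distances - 30) <= 1))
  expect_false(rb$empty)
  expect_warning(rb0 <- radial_boundary(matrix(0L, 9, 9), "OC", c(5, 5)), "empty")
  expect_true(all(rb0$distances == 0))
  expect_true(rb0$empty)
})

test_that("half-plane structure yields 0 backwards and the border distance forwards", {
  m <- matrix(0L, 21, 21); m[, 12:21] <- 1L
  rb <- radial_boundary(m, "OD", c(11, 11), 4)  # angles 0, 90, 180, 270
  expect_equal(rb$distances[3], 0)  # theta = pi: ray crosses no positive cell
  # theta = 0: out to the far edge of the border pixel
  expect_lt(abs(rb$distances[1] - 10.5), 0.5)
})

test_that("radial boundary agrees with a 100x finer ray-marching oracle", {
  for (s in 1:10) {
    m <- blob_mask(48, seed = s)
    coarse <- radial_boundary(m, "OD", c(24, 24), 24)$distances
    fine <- ray_march_fine(m, "OD", c(24, 24), 24, step = 0.005)
    expect_true(all(abs(coarse - fine) <= 0.5))
  }
})

test_that("BLE is zero for identical masks and matches concentric-disc geometry", {
  gt <- circle_mask(121, c(61, 61), 50)
  pred <- circle_mask(121, c(61, 61), 45)
  expect_equal(as.numeric(ble(gt, gt, "OD", c(61, 61))), 0)
  expect_equal(as.numeric(ble(pred, gt, "OD", c(61, 61))), 5, tolerance = 0.5)
  for (s in c(2, 7, 13)) {
    m <- blob_mask(48, seed = s)
    expect_equal(as.numeric(ble(m, m, "OD", c(24, 24))), 0)
  }
})

test_that("BLE of a shifted disc matches the high-resolution oracle", {
  gt <- circle_mask(121, c(61, 61), 40)
  pred <- circle_mask(121, c(71, 61), 40)  # shifted 10 px along +x
  got <- as.numeric(ble(pred, gt, "OD", c(61, 61)))
  dg <- ray_march_fine(gt, "OD", c(61, 61), 24, step = 0.01)
  d0 <- ray_march_fine(pred, "OD", c(61, 61), 24, step = 0.01)
  expect_equal(got, mean(abs(dg - d0)), tolerance = 0.5)
})

test_that("uniform erosion of a disc increases BLE by the erosion amount", {
  gt <- circle_mask(121, c(61, 61), 40)
  for (k in 1:5) {
    b <- as.numeric(ble(circle_mask(121, c(61, 61), 40 - k), gt, "OD", c(61, 61)))
    expect_equal(b, k, tolerance = 0.5)
  }
})

test_that("BLE is invariant under joint quarter-turn rotation of both masks", {
  gt <- blob_mask(49, seed = 3)
  pred <- blob_mask(49, seed = 4)
  rot <- function(m) t(m)[, rev(seq_len(ncol(m)))]
  b0 <- as.numeric(ble(pred, gt, "OD", c(25, 25)))
  b1 <- as.numeric(ble(rot(pred), rot(gt), "OD", c(25, 25)))
  expect_equal(b0, b1, tolerance = 0.5)
})

test_that("the printed square-root BLE form errors when the prediction overshoots", {
  gt <- circle_mask(61, c(31, 31), 20)
  inner <- circle_mask(61, c(31, 31), 15)
  outer <- circle_mask(61, c(31, 31), 25)
  v <- ble(inner, gt, "OD", c(31, 31), form = "signed_sqrt")
  expect_true(is.finite(v) && v > 0)
  expect_error(ble(outer, gt, "OD", c(31, 31), form = "signed_sqrt"), "undefined")
})

test_that("vertical CDR follows the pixel-extent convention", {
  m <- disc_cup_mask(121, c(61, 61), 50, 25)
  expect_equal(vertical_cdr(m), 51 / 101)
  cup_only <- m; cup_only[cup_only == 1L] <- 2L
  expect_equal(vertical_cdr(cup_only), 1)
  disc_only <- m; disc_only[disc_only == 2L] <- 1L
  expect_equal(vertical_cdr(disc_only), 0)
  expect_warning(v <- vertical_cdr(matrix(0L, 5, 5)), "disc absent")
  expect_true(is.na(v))
})

test_that("per-image evaluation and the dataset report have coherent columns", {
  gt <- disc_cup_mask(101, c(51, 51), 40, 20)
  pred <- disc_cup_mask(101, c(53, 51), 38, 19)
  row <- evaluate_masks(pred, gt)
  expect_true(all(c("F1_OD", "F1_OC", "BLE_OD", "BLE_OC", "CDR_pred", "CDR_gt") %in% names(row)))
  expect_true(all(row[grep("^(F1|ACC|SPC|SEN)", names(row))] >= 0 &
                    row[grep("^(F1|ACC|SPC|SEN)", names(row))] <= 1))
  rep <- metrics_report(list(pred, gt), list(gt, gt))
  expect_equal(nrow(rep$per_image), 2)
  expect_equal(rep$per_image$F1_OD[2], 1)
  expect_equal(rownames(rep$summary), c("mean", "sd"))
})
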