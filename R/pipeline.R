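# Experiment orchestration: configuration, the preprocess -> train ->
# predict -> inverse-warp -> evaluate workflow, the five-way ablation grid
# (baseline, +PT, +MSRCR-PT, +RSAP, +RSAP+MSRCR-PT) and a self-contained
# desk-scale experiment on synthetic data.

#' Experiment configuration
#'
#' @param model A [model_config()].
#' @param retinex A [retinex_params()].
#' @param augmentation Optional [augmentation_spec()]; `NULL` disables
#'   augmentation.
#' @param augment_copies Augmented copies added per training image when
#'   augmentation is enabled.
#' @param optimizer List with `lr`, `momentum`, `weight_decay`.
#' @param epochs Training epochs (reference protocol: 400).
#' @param batch_size Images per gradient update.
#' @param seed Master seed (weights, shuffling, split, augmentation).
#' @param use_msrcr Apply MSRCR enhancement before warping.
#' @param use_polar Train and predict in polar coordinates (predictions are
#'   mapped back to Cartesian space before scoring).
#' @param test_fraction Held-out fraction when no split manifest exists.
#' @return An `experiment_config` object.
#' @export
experiment_config <- function(model = model_config(),
                              retinex = retinex_params(),
                              augmentation = NULL, augment_copies = 1,
                              optimizer = list(lr = 0.001, momentum = 0.9, weight_decay = 5e-4),
                              epochs = 400, batch_size = 4, seed = 1,
                              use_msrcr = TRUE, use_polar = TRUE,
                              test_fraction = 0.25) {
  stopifnot(inherits(model, "model_config"), inherits(retinex, "retinex_params"))
  if (!is.null(augmentation)) stopifnot(inherits(augmentation, "augmentation_spec"))
  structure(list(model = model, retinex = retinex, augmentation = augmentation,
                 augment_copies = augment_copies, optimizer = optimizer,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 seed = as.integer(seed), use_msrcr = isTRUE(use_msrcr),
                 use_polar = isTRUE(use_polar), test_fraction = test_fraction),
            class = "experiment_config")
}

#' Save / load an experiment configuration as YAML
#'
#' The YAML round trip reproduces an identical configuration, so a saved
#' experiment can be re-run exactly.
#'
#' @param config An [experiment_config()].
#' @param path YAML file path.
#' @return `read_experiment_config` returns the configuration.
#' @export
write_experiment_config <- function(config, path) {
  plain <- rapply(unclass(config), function(x) x, how = "replace")
  plain$model <- unclass(plain$model)
  plain$retinex <- unclass(plain$retinex)
  if (!is.null(plain$augmentation)) plain$augmentation <- unclass(plain$augmentation)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  ml <- y$model
  ml$gic_conv_specs <- lapply(ml$gic_conv_specs, unlist)
  experiment_config(
    model = do.call(model_config, ml),
    retinex = do.call(retinex_params, y$retinex),
    augmentation = if (!is.null(y$augmentation)) do.call(augmentation_spec, y$augmentation),
    augment_copies = y$augment_copies, optimizer = y$optimizer,
    epochs = y$epochs, batch_size = y$batch_size, seed = y$seed,
    use_msrcr = y$use_msrcr, use_polar = y$use_polar,
    test_fraction = y$test_fraction)
}

# preprocess one sample according to the config; returns the network input
# pair plus what is needed to map a prediction back to Cartesian space
preprocess_sample <- function(sample, config) {
  img <- sample$image; mask <- sample$mask
  if (config$use_msrcr) img <- msrcr(img, config$retinex)
  S <- config$model$input_size
  if (config$use_polar) {
    ctr <- sample$center %||% disc_centroid(mask)
    rad <- max_inscribed_radius(ctr, nrow(mask), ncol(mask))
    grid <- polar_grid(ctr, rad, n_radii = S, n_angles = S)
    list(x = to_polar(img, grid, "bilinear"),
         y = matrix(as.integer(to_polar(mask, grid, "nearest")), S, S),
         grid = grid, orig_mask = mask, center = ctr)
  } else {
    list(x = resize_bilinear(img, S, S),
         y = matrix(as.integer(resize_nearest(mask, S, S)), S, S),
         grid = NULL, orig_mask = mask, center = sample$center)
  }
}

# map a network-space prediction back onto the original mask geometry
postprocess_prediction <- function(pred, prep) {
  if (!is.null(prep$grid)) {
    out <- from_polar(pred, prep$grid, dim(prep$orig_mask), "nearest")
  } else {
    out <- resize_nearest(pred, nrow(prep$orig_mask), ncol(prep$orig_mask))
  }
  matrix(as.integer(out), nrow(prep$orig_mask), ncol(prep$orig_mask))
}

# core fit/evaluate routine shared by run_pipeline and run_desk_experiment;
# train/test are lists of samples (image, mask, center)
fit_and_evaluate <- function(train, test, config, verbose = FALSE) {
  prep_tr <- lapply(train, preprocess_sample, config = config)
  if (!is.null(config$augmentation)) {
    aug <- list()
    for (k in seq_len(config$augment_copies)) {
      for (i in seq_along(train)) {
        a <- augment(train[[i]]$image, train[[i]]$mask, config$augmentation,
                     seed = config$seed + 1000 * k + i)
        aug[[length(aug) + 1L]] <- preprocess_sample(
          list(image = a$image, mask = a$mask, center = disc_centroid(a$mask)), config)
      }
    }
    prep_tr <- c(prep_tr, aug)
  }
  model <- rsap_net(config$model, seed = config$seed)
  losses <- train_model(model,
                        images = lapply(prep_tr, `[[`, "x"),
                        masks = lapply(prep_tr, `[[`, "y"),
                        epochs = config$epochs, lr = config$optimizer$lr,
                        momentum = config$optimizer$momentum,
                        weight_decay = config$optimizer$weight_decay,
                        batch_size = config$batch_size, seed = config$seed,
                        verbose = verbose)
  prep_te <- lapply(test, preprocess_sample, config = config)
  preds <- lapply(prep_te, function(p) postprocess_prediction(predict_mask(model, p$x), p))
  gts <- lapply(prep_te, `[[`, "orig_mask")
  centers <- lapply(prep_te, function(p) p$center %||% disc_centroid(p$orig_mask))
  report <- metrics_report(preds, gts, centers)
  list(model = model, report = report, losses = losses, predictions = preds,
       test_prep = prep_te)
}

#' Run a full segmentation experiment from a data directory
#'
#' Expects the layout `images/*.png` and `masks/*.png` with matching stems;
#' optional manifests `split_train.txt` / `split_test.txt` (one stem per
#' line) fix the split, otherwise a seeded random `test_fraction` split is
#' drawn. Executes optional MSRCR enhancement, optional polar warping,
#' optional augmentation, network training, prediction, inverse warping and
#' evaluation; writes predicted masks, a per-image metrics CSV, the
#' resolved configuration and a per-epoch loss log into `out_dir`.
#'
#' @param config An [experiment_config()].
#' @param data_dir Input directory.
#' @param out_dir Output directory (created if missing); `NULL` writes
#'   nothing.
#' @param verbose Print per-epoch losses.
#' @return A [metrics_report()] (invisibly also the trained model via
#'   attribute `"model"`).
#' @export
run_pipeline <- function(config, data_dir, out_dir = NULL, verbose = FALSE) {
  tr_manifest <- file.path(data_dir, "split_train.txt")
  te_manifest <- file.path(data_dir, "split_test.txt")
  if (file.exists(tr_manifest) && file.exists(te_manifest)) {
    train <- read_dataset(data_dir, tr_manifest)
    test <- read_dataset(data_dir, te_manifest)
  } else {
    all <- read_dataset(data_dir)
    n_te <- max(1L, round(length(all) * config$test_fraction))
    idx_te <- with_seed(config$seed, sample.int(length(all), n_te))
    train <- all[-idx_te]; test <- all[idx_te]
  }
  fit <- fit_and_evaluate(train, test, config, verbose = verbose)
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "predictions"), recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(fit$predictions)) {
      stem <- test[[i]]$stem %||% sprintf("img_%04d", i)
      write_mask(fit$predictions[[i]], file.path(out_dir, "predictions", paste0(stem, ".png")))
    }
    utils::write.csv(fit$report$per_image, file.path(out_dir, "report.csv"), row.names = FALSE)
    write_experiment_config(config, file.path(out_dir, "config.yaml"))
    writeLines(sprintf("epoch %d loss %.6f", seq_along(fit$losses), fit$losses),
               file.path(out_dir, "loss_log.txt"))
  }
  out <- fit$report
  attr(out, "model") <- fit$model
  out
}

#' Five-way ablation grid
#'
#' Runs the standard ablation ladder with a shared seed: baseline (plain
#' encoder-decoder with additive skips, no pre-processing), baseline + polar
#' transform (PT), baseline + MSRCR-PT, baseline + RSAP bridges, and the
#' full method (RSAP + MSRCR-PT).
#'
#' @param base_config An [experiment_config()]; its `use_*` flags and
#'   `rsap_depths` are overridden per row.
#' @param train,test Lists of samples (`image`, `mask`, `center`), e.g.
#'   from [generate_synthetic_dataset()] or [read_dataset()].
#' @param verbose Print progress.
#' @return `data.frame` with one row per configuration (F1 and BLE for OD
#'   and OC), in ladder order.
#' @export
ablation_grid <- function(base_config, train, test, verbose = FALSE) {
  variants <- list(
    list(name = "baseline", msrcr = FALSE, polar = FALSE, rsap = FALSE),
    list(name = "baseline+PT", msrcr = FALSE, polar = TRUE, rsap = FALSE),
    list(name = "baseline+MSRCR-PT", msrcr = TRUE, polar = TRUE, rsap = FALSE),
    list(name = "baseline+RSAP", msrcr = FALSE, polar = FALSE, rsap = TRUE),
    list(name = "RSAP-Net+MSRCR-PT", msrcr = TRUE, polar = TRUE, rsap = TRUE))
  rows <- lapply(variants, function(v) {
    cfg <- base_config
    cfg$use_msrcr <- v$msrcr; cfg$use_polar <- v$polar
    mc <- cfg$model
    mc$rsap_depths <- if (v$rsap) base_config$model$rsap_depths else c(0L, 0L, 0L)
    cfg$model <- mc
    if (verbose) message("ablation: ", v$name)
    fit <- fit_and_evaluate(train, test, cfg, verbose = FALSE)
    s <- fit$report$summary
    data.frame(method = v$name,
               F1_OD = s["mean", "F1_OD"], F1_OC = s["mean", "F1_OC"],
               BLE_OD = s["mean", "BLE_OD"], BLE_OC = s["mean", "BLE_OC"])
  })
  do.call(rbind, rows)
}

#' Desk-scale end-to-end experiment on synthetic data
#'
#' Generates a seed-fixed synthetic cohort (128 x 128 images), trains the
#' full method (MSRCR enhancement, polar warping, RSAP-Net) with SGD
#' (lr 0.001, momentum 0.9, weight decay 0.0005) and evaluates on a held-out
#' synthetic set in Cartesian space. Network widths are scaled to the desk
#' problem; the protocol (optimiser, loss, pipeline order) is the full one.
#'
#' @param seed Master seed.
#' @param n_train,n_test Cohort sizes.
#' @param epochs Training epochs.
#' @param image_size Synthetic image side length.
#' @param base_channels Width of the shallowest network stage.
#' @param verbose Print per-epoch losses.
#' @return List with `report` (a [metrics_report()]), `losses`, `model`,
#'   and the headline `od_f1`, `oc_f1`, `od_ble`, `oc_ble`.
#' @export
run_desk_experiment <- function(seed = 1, n_train = 200, n_test = 50,
                                epochs = 10, image_size = 128,
                                base_channels = 8, verbose = FALSE) {
  params <- synthetic_fundus_params(image_size = image_size, seed = seed)
  train <- generate_synthetic_dataset(n_train, params, seed = seed)
  test <- generate_synthetic_dataset(n_test, params, seed = seed + 100000L)
  cfg <- experiment_config(
    model = model_config(input_size = image_size, base_channels = base_channels),
    epochs = epochs, batch_size = 1, seed = seed,
    use_msrcr = TRUE, use_polar = TRUE)
  fit <- fit_and_evaluate(train, test, cfg, verbose = verbose)
  s <- fit$report$summary
  list(report = fit$report, losses = fit$losses, model = fit$model,
       od_f1 = s["mean", "F1_OD"], oc_f1 = s["mean", "F1_OC"],
       od_ble = s["mean", "BLE_OD"], oc_ble = s["mean", "BLE_OC"])
}
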