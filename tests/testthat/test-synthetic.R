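test_that("generation is a deterministic function of the seed", {
  p <- synthetic_fundus_params()
  a <- generate_synthetic_fundus(p, seed = 12)
  b <- generate_synthetic_fundus(p, seed = 12)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  c <- generate_synthetic_fundus(p, seed = 13)
  expect_false(identical(a$mask, c$mask))
})

test_that("generated masks are well-formed with the cup strictly inside the disc", {
  for (s in 1:10) {
    g <- generate_synthetic_fundus(synthetic_fundus_params(), seed = s)
    expect_true(all(g$mask %in% 0:2))
    expect_gt(sum(g$mask == 2), 0)
    expect_gt(sum(g$mask == 1), 0)  # a visible disc rim remains around the cup
    # cup bounding box strictly inside the disc bounding box
    cup_rows <- range(which(apply(g$mask == 2, 1, any)))
    disc_rows <- range(which(apply(g$mask >= 1, 1, any)))
    cup_cols <- range(which(apply(g$mask == 2, 2, any)))
    disc_cols <- range(which(apply(g$mask >= 1, 2, any)))
    expect_true(cup_rows[1] > disc_rows[1] && cup_rows[2] < disc_rows[2])
    expect_true(cup_cols[1] > disc_cols[1] && cup_cols[2] < disc_cols[2])
    expect_equal(dim(g$image), c(128, 128, 3))
    expect_true(all(g$image >= 0 & g$image <= 255))
  }
})

test_that("a pinned CDR is realised by the mask within rasterisation tolerance", {
  p <- synthetic_fundus_params(cdr_range = c(0.5, 0.5), disc_radius_range = c(30, 30))
  for (s in 1:5) {
    g <- generate_synthetic_fundus(p, seed = s)
    expect_lt(abs(vertical_cdr(g$mask) - 0.5), 0.02)
  }
})

test_that("measured CDRs are close to uniform over the configured range", {
  p <- synthetic_fundus_params(cdr_range = c(0.3, 0.8))
  cdrs <- vapply(1:50, function(s) vertical_cdr(generate_synthetic_fundus(p, seed = s)$mask),
                 numeric(1))
  expect_true(all(cdrs >= 0.28 & cdrs <= 0.82))
  ks <- suppressWarnings(stats::ks.test(cdrs, "punif", 0.3, 0.8))
  expect_lt(unname(ks$statistic), 0.25)
})

test_that("parameter validation rejects impossible geometry", {
  expect_error(synthetic_fundus_params(cdr_range = c(0, 0.5)), "cdr_range")
  expect_error(synthetic_fundus_params(image_size = 64, disc_radius_range = c(40, 60)),
               "fit")
})

test_that("identity augmentation reduces to a resize", {
  mask <- disc_cup_mask(101, c(51, 51), 30, 15)
  set.seed(31)
  img <- array(runif(101 * 101 * 3, 0, 255), c(101, 101, 3))
  spec <- augmentation_spec(crop_sizes = 101, hflip = 0, vflip = 0,
                            rotation_range = c(0, 0), output_size = 101)
  out <- augment(img, mask, spec, seed = 1)
  expect_equal(out$image, img, tolerance = 1e-12)
  expect_identical(out$mask, mask)
})

test_that("a horizontal flip applied twice recovers the original crop", {
  mask <- disc_cup_mask(101, c(51, 51), 30, 15)
  set.seed(32)
  img <- array(runif(101 * 101 * 3, 0, 255), c(101, 101, 3))
  spec <- augmentation_spec(crop_sizes = 101, hflip = 1, vflip = 0,
                            rotation_range = c(0, 0), output_size = 101)
  once <- augment(img, mask, spec, seed = 2)
  twice <- augment(once$image, once$mask, spec, seed = 3)
  expect_equal(twice$image, img, tolerance = 1e-12)
  expect_identical(twice$mask, mask)
})

test_that("rotation by 90 degrees keeps the CDR of a circular mask", {
  mask <- disc_cup_mask(101, c(51, 51), 30, 15)
  set.seed(33)
  img <- array(runif(101 * 101 * 3, 0, 255), c(101, 101, 3))
  spec <- augmentation_spec(crop_sizes = 101, hflip = 0, vflip = 0,
                            rotation_range = c(90, 90), output_size = 101)
  out <- augment(img, mask, spec, seed = 4)
  expect_equal(vertical_cdr(out$mask), vertical_cdr(mask), tolerance = 0.02)
})

test_that("augmentation and polar warping preserve label closure and nesting", {
  p <- synthetic_fundus_params()
  spec <- augmentation_spec(crop_sizes = c(96, 128, 160), output_size = 96)
  for (s in 1:100) {
    g <- generate_synthetic_fundus(p, seed = 400 + s)
    a <- augment(g$image, g$mask, spec, seed = s)
    expect_true(all(a$mask %in% 0:2))
    grid <- polar_grid(g$center, fundusseg:::max_inscribed_radius(g$center, 128, 128), 64, 64)
    pm <- to_polar(g$mask, grid, "nearest")
    expect_true(all(pm %in% 0:2))
    if (any(a$mask == 2)) {
      cup_rows <- range(which(apply(a$mask == 2, 1, any)))
      disc_rows <- range(which(apply(a$mask >= 1, 1, any)))
      expect_true(cup_rows[1] >= disc_rows[1] && cup_rows[2] <= disc_rows[2])
    }
  }
})

test_that("augmenting a mask without disc pixels is an error", {
  expect_error(augment(array(0, c(8, 8, 3)), matrix(0L, 8, 8)), "disc")
})

test_that("mask files round trip through the 0/128/255 encoding", {
  tmp <- tempfile(fileext = ".png")
  on.exit(unlink(tmp))
  mask <- disc_cup_mask(33, c(17, 17), 12, 6)
  write_mask(mask, tmp)
  expect_identical(read_mask(tmp), mask)
  # all-cup file
  write_mask(matrix(2L, 5, 5), tmp)
  expect_identical(read_mask(tmp), matrix(2L, 5, 5))
  # a file with a stray value is rejected, naming the value
  png::writePNG(matrix(37 / 255, 4, 4), tmp)
  expect_error(read_mask(tmp), "37")
})

test_that("fundus images round trip through PNG within quantisation error", {
  tmp <- tempfile(fileext = ".png")
  on.exit(unlink(tmp))
  set.seed(34)
  img <- array(runif(16 * 16 * 3, 0, 255), c(16, 16, 3))
  write_fundus(img, tmp)
  expect_equal(read_fundus(tmp), img, tolerance = 1)
})

test_that("dataset writing produces the standard directory layout", {
  dir <- tempfile()
  on.exit(unlink(dir, recursive = TRUE))
  p <- synthetic_fundus_params(image_size = 64, disc_radius_range = c(14, 20))
  generate_synthetic_dataset(3, p, seed = 5, dir = dir)
  expect_length(list.files(file.path(dir, "images")), 3)
  expect_length(list.files(file.path(dir, "masks")), 3)
  ds <- fundusseg:::read_dataset(dir)
  expect_length(ds, 3)
  expect_true(all(ds[[1]]$mask %in% 0:2))
})
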