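test_that("single-scale Retinex is zero on constants and single pixels", {
  expect_equal(max(abs(single_scale_retinex(matrix(100, 8, 8), sigma = 3))), 0)
  expect_equal(single_scale_retinex(matrix(50, 1, 1), sigma = 5), matrix(0, 1, 1))
})

test_that("single-scale Retinex matches a dense-convolution oracle", {
  img <- matrix(0, 5, 5); img[3, 3] <- 255
  out <- single_scale_retinex(img, sigma = 1, epsilon = 1)
  blur <- dense_gauss_blur(img, 1)
  expect_equal(out, log(img + 1) - log(blur + 1), tolerance = 1e-12)
  # centre value in closed form: log(256) - log(1 + 255 * g00)
  r <- 3; k1 <- exp(-0.5 * (-r:r)^2); k1 <- k1 / sum(k1)
  g00 <- k1[r + 1]^2
  expect_equal(out[3, 3], log(256) - log(1 + 255 * g00), tolerance = 1e-12)

  set.seed(11)
  rnd <- matrix(runif(9 * 7, 0, 255), 9, 7)
  expect_equal(single_scale_retinex(rnd, 2, 1),
               log(rnd + 1) - log(dense_gauss_blur(rnd, 2) + 1), tolerance = 1e-12)
})

test_that("SSR rejects invalid input", {
  expect_error(single_scale_retinex(matrix(1, 4, 4), sigma = 0), "sigma")
  expect_error(single_scale_retinex(matrix(1, 4, 4), sigma = -2), "sigma")
  expect_error(single_scale_retinex(matrix(numeric(0), 0, 0), 1), "empty")
})

test_that("SSR with epsilon = 0 is invariant to global intensity scaling", {
  set.seed(3)
  img <- matrix(runif(16 * 16, 10, 255), 16, 16)
  for (k in c(0.5, 2, 7)) {
    expect_equal(single_scale_retinex(k * img, 4, epsilon = 0),
                 single_scale_retinex(img, 4, epsilon = 0), tolerance = 1e-10)
  }
})

test_that("multi-scale Retinex reduces to SSR at one scale and averages at two", {
  set.seed(4)
  img <- matrix(runif(16 * 16, 0, 255), 16, 16)
  p1 <- retinex_params(scales = 5, weights = 1)
  expect_equal(multi_scale_retinex(img, p1), single_scale_retinex(img, 5, p1$epsilon))

  p2 <- retinex_params(scales = c(3, 9), weights = c(0.5, 0.5))
  ssr <- (single_scale_retinex(img, 3, 1) + single_scale_retinex(img, 9, 1)) / 2
  expect_equal(multi_scale_retinex(img, p2), ssr, tolerance = 1e-12)
  expect_equal(max(abs(multi_scale_retinex(matrix(42, 8, 8), p2))), 0)
})

test_that("retinex parameter validation catches inconsistent settings", {
  expect_error(retinex_params(scales = c(5, 10), weights = 1), "equal length")
  expect_error(retinex_params(scales = -1), "positive")
  expect_error(retinex_params(clip = c(99, 1)), "clip")
  expect_error(retinex_params(epsilon = 0), "epsilon")
  # weights normalize to one
  expect_equal(sum(retinex_params(weights = c(2, 5, 3))$weights), 1)
})

test_that("MSRCR maps constant and gray images to constants", {
  out <- msrcr(array(77, c(12, 12, 3)))
  expect_equal(dim(out), c(12, 12, 3))
  expect_true(all(out == 127.5))
  # all-zero image: defined constant output, not an exception
  expect_true(all(msrcr(array(0, c(8, 8, 3))) == 127.5))
})

test_that("MSRCR rejects grayscale input and preserves shape/determinism", {
  expect_error(msrcr(matrix(1, 8, 8)), "3-channel")
  expect_error(msrcr(array(1, c(8, 8, 1))), "3-channel")
  set.seed(9)
  img <- array(runif(16 * 16 * 3, 0, 255), c(16, 16, 3))
  o1 <- msrcr(img); o2 <- msrcr(img)
  expect_identical(o1, o2)
  expect_equal(dim(o1), dim(img))
})

test_that("MSRCR with full-range clip stretches each channel to [0, 255]", {
  set.seed(10)
  img <- array(runif(20 * 20 * 3, 5, 250), c(20, 20, 3))
  out <- msrcr(img, retinex_params(gain = 1, offset = 0, clip = c(0, 100)))
  for (c in 1:3) {
    expect_equal(min(out[, , c]), 0)
    expect_equal(max(out[, , c]), 255)
  }
})

test_that("MSRCR sharpens the disc/background boundary of a synthetic disc", {
  d <- disc_fixture()
  enhanced <- msrcr(d$img)
  expect_gt(ring_contrast(enhanced, d$cc, d$radius),
            ring_contrast(d$img, d$cc, d$radius))
})
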