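test_that("dilated convolution output sizes follow the closed form", {
  expect_equal(dilated_out_size(512, 2, 2, 3, 1), 512L)   # "same" padding, d=2 k=3
  expect_equal(dilated_out_size(512, 0, 1, 2, 2), 256L)   # 2x2 stride-2 branch
  expect_equal(dilated_out_size(7, 0, 1, 3, 1), 5L)
  expect_equal(dilated_out_size(16, 0, 1, 5, 5), 3L)      # 5x5 pool, stride = kernel
  expect_error(dilated_out_size(4, 0, 1, 8, 1), "non-positive")
  expect_error(dilated_out_size(0, 0, 1, 3, 1), "invalid")
})

test_that("model configuration enforces its invariants", {
  expect_error(model_config(input_size = 100), "divisible by 32")
  expect_error(model_config(n_classes = 2), "3 classes")
  expect_error(model_config(rsap_depths = c(1, 1)), "exactly 3")
  cfg <- model_config(input_size = 64, base_channels = 4)
  expect_equal(cfg$encoder_stage_channels, c(4L, 8L, 16L, 32L, 64L))
  expect_equal(cfg$mdc_dilations, c(1L, 2L, 5L))
  expect_equal(cfg$rsap_depths, c(3L, 2L, 1L))
})

test_that("cross-entropy matches the closed-form arithmetic", {
  expect_equal(cross_entropy_loss(c(0, 0, 0), 0), log(3), tolerance = 1e-12)
  expect_equal(cross_entropy_loss(c(1, 2, 3), 2), -3 + log(exp(1) + exp(2) + exp(3)),
               tolerance = 1e-12)
  # saturating limit: confident correct logit drives the loss to zero
  expect_lt(cross_entropy_loss(c(50, 0, 0), 0), 1e-15)
  expect_error(cross_entropy_loss(c(0, 0, 0), 3), "class")
  # array form averages the per-pixel vector form
  set.seed(6)
  lg <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  tg <- matrix(sample(0:2, 16, TRUE), 4, 4)
  per_pixel <- vapply(1:16, function(i) {
    cross_entropy_loss(lg[cbind(rep(row(tg)[i], 3), rep(col(tg)[i], 3), 1:3)], tg[i])
  }, numeric(1))
  expect_equal(cross_entropy_loss(lg, tg), mean(per_pixel), tolerance = 1e-12)
  # positivity and shift invariance (log-sum-exp identity)
  expect_gt(cross_entropy_loss(lg, tg), 0)
  expect_equal(cross_entropy_loss(lg + 11.3, tg), cross_entropy_loss(lg, tg),
               tolerance = 1e-10)
})

test_that("spatial attention has the contracted shape and frozen-kernel behaviour", {
  set.seed(7)
  x <- array(rnorm(5 * 6 * 4), c(5, 6, 4))
  a <- spatial_attention(x)
  expect_equal(dim(a), c(5, 6, 1))
  # kernel selecting the centre tap of the max-pooled plane reproduces
  # LeakyReLU(channel max)
  w_max <- matrix(0, 18, 1); w_max[5, 1] <- 1  # (ki=2, kj=2, plane 1)
  mx <- apply(x, c(1, 2), max)
  expect_equal(spatial_attention(x, weights = w_max, slope = 0.01)[, , 1],
               ifelse(mx > 0, mx, 0.01 * mx), tolerance = 1e-12)
  # with identical channels the max and average planes coincide, so a
  # difference kernel gives exactly zero
  xeq <- array(rep(matrix(rnorm(30), 5, 6), 4), c(5, 6, 4))
  w_diff <- matrix(0, 18, 1); w_diff[5, 1] <- 1; w_diff[14, 1] <- -1
  expect_equal(max(abs(spatial_attention(xeq, weights = w_diff))), 0)
})

test_that("MDC preserves shape, passes identity at zero weights, and has a 17 px receptive field", {
  set.seed(8)
  x <- array(rnorm(33 * 33 * 2), c(33, 33, 2))
  expect_equal(dim(mdc_block(x)), dim(x))
  expect_equal(mdc_block(x, zero_weights = TRUE), x)
  # receptive field of the deepest cascade (dilations 1+2+5, k=3): the
  # impulse response of the bare convolution cascade has support radius
  # exactly 8, i.e. diameter 17 px
  set.seed(2)
  convs <- lapply(c(1, 2, 5), function(d) fundusseg:::nn_conv(1, 1, 3, dil = d))
  tp <- fundusseg:::nn_tape()
  impulse <- array(0, c(33, 33, 1)); impulse[17, 17, 1] <- 1
  h <- fundusseg:::nn_node(tp, impulse)
  for (cv in convs) h <- cv$forward(h, tp)
  resp <- h$value[, , 1] != 0
  on_rows <- range(which(apply(resp, 1, any)))
  on_cols <- range(which(apply(resp, 2, any)))
  expect_equal(on_rows, c(17 - 8, 17 + 8))
  expect_equal(on_cols, c(17 - 8, 17 + 8))
})

test_that("GIC adds exactly four channels and handles constant input", {
  set.seed(9)
  x <- array(rnorm(16 * 16 * 3), c(16, 16, 3))
  y <- gic_block(x)
  expect_equal(dim(y), c(16, 16, 7))
  expect_equal(y[, , 1:3], x)  # input is passed through unchanged
  # constant input: pooling branches give constant maps after upsampling
  xc <- array(2, c(12, 12, 2))
  yc <- gic_block(xc)
  for (c in 5:6) expect_lt(diff(range(yc[, , c])), 1e-9)
  expect_error(gic_block(array(0, c(4, 4, 2))), "spatial size")
})

test_that("forward pass honours the scale and channel contracts at reduced size", {
  cfg <- model_config(input_size = 64, base_channels = 4)
  m <- rsap_net(cfg, seed = 2)
  x <- array(runif(64 * 64 * 3, -1, 1), c(64, 64, 3))
  fw <- nn_forward(m, x)
  expect_equal(fw$encoder_sizes, c(32, 16, 8, 4, 2))
  expect_equal(dim(fw$logits), c(64, 64, 3))
  expect_error(nn_forward(m, array(0, c(32, 32, 3))), "input must be")
})

test_that("construction and forward are deterministic under a fixed seed", {
  cfg <- model_config(input_size = 64, base_channels = 4)
  m1 <- rsap_net(cfg, seed = 5); m2 <- rsap_net(cfg, seed = 5)
  expect_equal(n_params(m1), n_params(m2))
  for (i in seq_along(m1$params))
    expect_identical(m1$params[[i]]$value, m2$params[[i]]$value)
  x <- array(runif(64 * 64 * 3, -1, 1), c(64, 64, 3))
  expect_identical(nn_forward(m1, x)$logits, nn_forward(m2, x)$logits)
})

test_that("the RSAP bridges follow the configured depths and degrade to plain skips", {
  m <- rsap_net(model_config(input_size = 64, base_channels = 4), seed = 1)
  expect_length(m$bridges, 3)
  expect_equal(vapply(m$bridges, function(b) length(b$blocks), integer(1)), c(3L, 2L, 1L))
  # depth 0: the bridge forwards its input untouched (additive skip baseline)
  p0 <- fundusseg:::make_rsap_path(4, 0, 0.01)
  tp <- fundusseg:::nn_tape()
  xn <- fundusseg:::nn_node(tp, array(1, c(4, 4, 4)))
  expect_identical(p0$forward(xn, tp), xn)
})

test_that("analytic gradients match finite differences through the full network", {
  cfg <- model_config(input_size = 32, base_channels = 2)
  m <- rsap_net(cfg, seed = 3)
  set.seed(30)
  x <- array(runif(32 * 32 * 3, -1, 1), c(32, 32, 3))
  tg <- matrix(sample(0:2, 32 * 32, TRUE), 32, 32)
  fw <- nn_forward(m, x, tg)
  fundusseg:::nn_backward(fw$tape, fw$loss_node)
  for (pi in c(1, 11, 47, length(m$params))) {
    p <- m$params[[pi]]
    expect_false(is.null(p$grad))
    i <- which.max(abs(p$grad))
    eps <- 1e-5; old <- p$value[i]
    p$value[i] <- old + eps; l1 <- nn_forward(m, x, tg)$loss
    p$value[i] <- old - eps; l2 <- nn_forward(m, x, tg)$loss
    p$value[i] <- old
    expect_equal(p$grad[i], (l1 - l2) / (2 * eps), tolerance = 1e-4)
  }
  fundusseg:::zero_grads(m$params)
})
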