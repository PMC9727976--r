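# RSAP-Net: a U-shaped encoder-decoder for joint disc/cup segmentation.
# The encoder is a stem convolution plus four residual stages, each followed
# by 2x2 max pooling (five downsampled scales, S/2 .. S/32). The bottleneck
# combines a multi-branch dilated-convolution block (MDC, cascaded dilation
# rates 1/2/5) with a global information coding block (GIC, multi-size
# pooled single-channel summaries). Three residual spatial-attention paths
# (RSAP) bridge the three shallowest encoder scales to the decoder, whose
# blocks use two 1x1 convolutions and a stride-2 3x3 transposed convolution.
# The head emits raw three-class logits (background / disc / cup).

#' Architecture hyperparameters
#'
#' @param input_size Input side length in pixels; must be divisible by 32.
#' @param base_channels Width of the shallowest stage; stage widths default
#'   to `base_channels * c(1, 2, 4, 8, 16)`.
#' @param encoder_stage_channels Five integers, channel widths at scales
#'   S/2, S/4, S/8, S/16, S/32.
#' @param mdc_dilations Dilation rates of the cascaded MDC branches.
#' @param gic_pool_sizes Kernel (= stride) sizes of the two GIC max-pooling
#'   branches.
#' @param gic_conv_specs List of `c(kernel, stride)` pairs for the two GIC
#'   convolution branches.
#' @param rsap_depths Three integers: residual-block count per bridge path,
#'   shallowest first. Shallower bridges are deeper because the feature gap
#'   between encoder and decoder is largest there. A depth of 0 degrades the
#'   bridge to a plain additive skip (the ablation baseline).
#' @param n_classes Number of output classes; fixed at 3.
#' @param leaky_slope Negative slope of every LeakyReLU activation.
#' @return A `model_config` object.
#' @export
model_config <- function(input_size = 512, base_channels = 32,
                         encoder_stage_channels = base_channels * c(1, 2, 4, 8, 16),
                         mdc_dilations = c(1, 2, 5),
                         gic_pool_sizes = c(5, 6),
                         gic_conv_specs = list(c(2, 2), c(3, 3)),
                         rsap_depths = c(3, 2, 1),
                         n_classes = 3, leaky_slope = 0.01) {
  if (input_size %% 32 != 0) stop("input_size must be divisible by 32")
  if (n_classes != 3) stop("the segmentation task has exactly 3 classes")
  if (length(rsap_depths) != 3) stop("rsap_depths must have exactly 3 entries")
  if (length(encoder_stage_channels) != 5) stop("need 5 encoder stage channel widths")
  structure(list(input_size = as.integer(input_size),
                 base_channels = as.integer(base_channels),
                 encoder_stage_channels = as.integer(encoder_stage_channels),
                 mdc_dilations = as.integer(mdc_dilations),
                 gic_pool_sizes = as.integer(gic_pool_sizes),
                 gic_conv_specs = gic_conv_specs,
                 rsap_depths = as.integer(rsap_depths),
                 n_classes = as.integer(n_classes),
                 leaky_slope = leaky_slope),
            class = "model_config")
}

#' Output size of a (dilated) convolution
#'
#' `floor((w_in + 2p - d*(k-1) - 1)/s) + 1`.
#'
#' @param w_in Input width (positive integer).
#' @param p Padding (>= 0).
#' @param d Dilation rate.
#' @param k Kernel size.
#' @param s Stride.
#' @return Output width; errors if non-positive.
#' @export
#' @examples
#' dilated_out_size(512, 2, 2, 3, 1)  # "same" padding for d = 2, k = 3
dilated_out_size <- function(w_in, p, d, k, s) {
  if (w_in < 1 || d < 1 || k < 1 || s < 1 || p < 0) stop("invalid convolution geometry")
  out <- (w_in + 2 * p - d * (k - 1) - 1) %/% s + 1
  if (out < 1) stop("convolution output size is non-positive")
  as.integer(out)
}

#' Three-class cross-entropy loss
#'
#' `Loss(x, c) = -x[c] + log(sum_j exp(x[j]))` per pixel, averaged over
#' pixels. Class map: 0 background, 1 optic disc, 2 optic cup. Accepts a
#' single logit vector with a scalar target, or an `H x W x C` logit array
#' with an `H x W` label matrix.
#'
#' @param logits Length-C numeric vector or `H x W x C` array (raw,
#'   pre-softmax).
#' @param target Scalar class label or `H x W` matrix over `0..C-1`.
#' @return Nonnegative scalar loss.
#' @export
#' @examples
#' cross_entropy_loss(c(0, 0, 0), 0)  # log(3)
cross_entropy_loss <- function(logits, target) {
  if (is.null(dim(logits))) {
    if (length(target) != 1 || !(target %in% 0:(length(logits) - 1)))
      stop("target must be a single class label in 0..C-1")
    m <- max(logits)
    return(-logits[target + 1] + m + log(sum(exp(logits - m))))
  }
  C <- dim(logits)[3]
  if (!all(target %in% 0:(C - 1))) stop("target labels outside 0..C-1")
  m <- apply(logits, c(1, 2), max)
  lse <- m + log(apply(exp(logits - array(m, dim = dim(logits))), c(1, 2), sum))
  H <- dim(logits)[1]; W <- dim(logits)[2]
  picked <- logits[cbind(rep(seq_len(H), W), rep(seq_len(W), each = H), as.vector(target) + 1)]
  mean(lse - picked)
}

# ---- building blocks --------------------------------------------------------

make_res_block <- function(cin, cout, slope) {
  blk <- list(conv1 = nn_conv(cin, cout, 3), bn1 = nn_bn(cout),
              conv2 = nn_conv(cout, cout, 3), bn2 = nn_bn(cout),
              proj = if (cin != cout) nn_conv(cin, cout, 1) else NULL,
              slope = slope)
  blk$layers <- Filter(Negate(is.null),
                       list(blk$conv1, blk$bn1, blk$conv2, blk$bn2, blk$proj))
  blk$forward <- function(x, tape) {
    h <- nn_lrelu_op(blk$bn1$forward(blk$conv1$forward(x, tape), tape), tape, slope)
    h <- blk$bn2$forward(blk$conv2$forward(h, tape), tape)
    idn <- if (is.null(blk$proj)) x else blk$proj$forward(x, tape)
    nn_lrelu_op(nn_add_op(h, idn, tape), tape, slope)
  }
  blk
}

make_attention <- function(slope) {
  att <- list(conv = nn_conv(2, 1, 3), slope = slope)
  att$layers <- list(att$conv)
  att$forward <- function(x, tape) {
    mx <- nn_chanmax_op(x, tape)
    av <- nn_chanmean_op(x, tape)
    nn_lrelu_op(att$conv$forward(nn_concat_op(list(mx, av), tape), tape), tape, slope)
  }
  att
}

make_rsap_path <- function(c, depth, slope) {
  path <- list(depth = depth,
               blocks = if (depth > 0) lapply(seq_len(depth), function(i) make_res_block(c, c, slope)) else list(),
               attention = if (depth > 0) make_attention(slope) else NULL)
  path$layers <- c(unlist(lapply(path$blocks, function(b) b$layers), recursive = FALSE),
                   if (!is.null(path$attention)) path$attention$layers)
  path$forward <- function(x, tape) {
    if (depth == 0) return(x)  # plain additive skip (ablation baseline)
    g <- x
    for (b in path$blocks) g <- b$forward(g, tape)
    a <- path$attention$forward(g, tape)
    nn_mul_map_op(g, a, tape)
  }
  path
}

make_mdc <- function(c, dilations, slope) {
  nd <- length(dilations)
  # cascaded branches: branch i applies convs with dilations[1..i], then 1x1
  branches <- lapply(seq_len(nd), function(i) {
    convs <- lapply(seq_len(i), function(j) nn_conv(c, c, 3, dil = dilations[j]))
    bns <- lapply(seq_len(i), function(j) nn_bn(c))
    one <- nn_conv(c, c, 1)
    list(convs = convs, bns = bns, one = one,
         layers = c(convs, bns, list(one)))
  })
  mdc <- list(branches = branches, slope = slope, dilations = dilations)
  mdc$layers <- unlist(lapply(branches, function(b) b$layers), recursive = FALSE)
  mdc$forward <- function(x, tape) {
    out <- x  # identity branch
    for (b in branches) {
      h <- x
      for (j in seq_along(b$convs))
        h <- nn_lrelu_op(b$bns[[j]]$forward(b$convs[[j]]$forward(h, tape), tape), tape, slope)
      out <- nn_add_op(out, b$one$forward(h, tape), tape)
    }
    out
  }
  mdc
}

make_gic <- function(c, pool_sizes, conv_specs, spatial, slope) {
  # degrade branch windows gracefully when the bottleneck is smaller than the
  # nominal windows (small input sizes)
  pool_sizes <- pmin(pool_sizes, spatial)
  conv_specs <- lapply(conv_specs, function(ks) c(min(ks[1], spatial), min(ks[2], spatial)))
  convs <- lapply(conv_specs, function(ks) nn_conv(c, c, ks[1], stride = ks[2], pad = 0))
  ones <- lapply(seq_len(length(conv_specs) + length(pool_sizes)),
                 function(i) nn_conv(c, 1, 1))
  gic <- list(convs = convs, ones = ones, pool_sizes = pool_sizes,
              conv_specs = conv_specs, spatial = spatial, slope = slope)
  gic$layers <- c(convs, ones)
  gic$forward <- function(x, tape) {
    H <- dim(x$value)[1]; W <- dim(x$value)[2]
    maps <- list()
    for (i in seq_along(convs)) {
      h <- nn_lrelu_op(convs[[i]]$forward(x, tape), tape, slope)
      h <- ones[[i]]$forward(h, tape)
      maps[[length(maps) + 1L]] <- nn_upsample_op(h, tape, H, W)
    }
    for (j in seq_along(pool_sizes)) {
      h <- nn_maxpool_op(x, tape, k = pool_sizes[j], s = pool_sizes[j])
      h <- ones[[length(convs) + j]]$forward(h, tape)
      maps[[length(maps) + 1L]] <- nn_upsample_op(h, tape, H, W)
    }
    nn_concat_op(c(list(x), maps), tape)
  }
  gic
}

make_dec_block <- function(cin, cmid, cout, slope) {
  dec <- list(one1 = nn_conv(cin, cmid, 1), bn1 = nn_bn(cmid),
              one2 = nn_conv(cmid, cout, 1), bn2 = nn_bn(cout),
              up = nn_convt(cout, cout), bn3 = nn_bn(cout), slope = slope)
  dec$layers <- list(dec$one1, dec$bn1, dec$one2, dec$bn2, dec$up, dec$bn3)
  dec$forward <- function(x, tape) {
    h <- nn_lrelu_op(dec$bn1$forward(dec$one1$forward(x, tape), tape), tape, slope)
    h <- nn_lrelu_op(dec$bn2$forward(dec$one2$forward(h, tape), tape), tape, slope)
    nn_lrelu_op(dec$bn3$forward(dec$up$forward(h, tape), tape), tape, slope)
  }
  dec
}

# ---- the network ------------------------------------------------------------

#' Construct an RSAP-Net model
#'
#' Builds the full network with He fan-in initialisation under the given
#' seed. The returned model environment exposes `forward()` (see
#' [nn_forward()]), its `config`, the list of `params`, and the three
#' `bridges`.
#'
#' @param config A [model_config()].
#' @param seed Integer seed for weight initialisation.
#' @return A `rsap_net` model object.
#' @export
rsap_net <- function(config = model_config(), seed = 1) {
  stopifnot(inherits(config, "model_config"))
  ch <- config$encoder_stage_channels
  sl <- config$leaky_slope
  bottleneck <- config$input_size %/% 32L
  m <- new.env(parent = emptyenv())
  m$config <- config
  with_seed(seed, {
    m$stem_conv <- nn_conv(3, ch[1], 3); m$stem_bn <- nn_bn(ch[1])
    m$enc <- list(make_res_block(ch[1], ch[2], sl), make_res_block(ch[2], ch[3], sl),
                  make_res_block(ch[3], ch[4], sl), make_res_block(ch[4], ch[5], sl))
    m$mdc <- make_mdc(ch[5], config$mdc_dilations, sl)
    m$gic <- make_gic(ch[5], config$gic_pool_sizes, config$gic_conv_specs, bottleneck, sl)
    # bridges at the three shallowest scales; rsap_depths is shallowest-first
    m$bridges <- list(make_rsap_path(ch[1], config$rsap_depths[1], sl),
                      make_rsap_path(ch[2], config$rsap_depths[2], sl),
                      make_rsap_path(ch[3], config$rsap_depths[3], sl))
    cgic <- ch[5] + length(config$gic_pool_sizes) + length(config$gic_conv_specs)
    m$dec <- list(make_dec_block(cgic, ch[5], ch[4], sl),   # S/32 -> S/16
                  make_dec_block(ch[4], ch[4], ch[3], sl),  # S/16 -> S/8
                  make_dec_block(ch[3], ch[3], ch[2], sl),  # S/8  -> S/4
                  make_dec_block(ch[2], ch[2], ch[1], sl))  # S/4  -> S/2
    m$head_up <- nn_convt(ch[1], ch[1]); m$head_bn <- nn_bn(ch[1])
    m$head_out <- nn_conv(ch[1], config$n_classes, 1)
  })
  blocks <- c(list(m$stem_conv, m$stem_bn), unlist(lapply(m$enc, function(b) b$layers), recursive = FALSE),
              m$mdc$layers, m$gic$layers,
              unlist(lapply(m$bridges, function(b) b$layers), recursive = FALSE),
              unlist(lapply(m$dec, function(b) b$layers), recursive = FALSE),
              list(m$head_up, m$head_bn, m$head_out))
  m$params <- collect_params(blocks)
  class(m) <- "rsap_net"
  m
}

#' Forward pass of an RSAP-Net
#'
#' Runs one image through the network. With a `target` label matrix the
#' cross-entropy loss node is built on the same tape so [nn_backward()] can
#' backpropagate through it.
#'
#' @param model An [rsap_net()] model.
#' @param x `S x S x 3` input array (already normalized).
#' @param target Optional `S x S` label matrix over `{0, 1, 2}`.
#' @return List with `logits` (`S x S x 3` array), `loss` (scalar or NULL),
#'   `loss_node`, `tape`, and `encoder_sizes` (spatial side of the five
#'   encoder scales).
#' @export
nn_forward <- function(model, x, target = NULL) {
  S <- model$config$input_size
  if (!all(dim(x) == c(S, S, 3)))
    stop("input must be ", S, " x ", S, " x 3 for this configuration")
  sl <- model$config$leaky_slope
  tp <- nn_tape()
  xn <- nn_node(tp, x)
  h <- nn_lrelu_op(model$stem_bn$forward(model$stem_conv$forward(xn, tp), tp), tp, sl)
  skips <- list(); sizes <- integer(5)
  s <- nn_maxpool_op(h, tp, 2)            # S/2
  skips[[1]] <- s; sizes[1] <- dim(s$value)[1]
  for (i in 1:4) {
    s <- nn_maxpool_op(model$enc[[i]]$forward(s, tp), tp, 2)
    if (i < 4) skips[[i + 1]] <- s
    sizes[i + 1] <- dim(s$value)[1]
  }
  b <- model$gic$forward(model$mdc$forward(s, tp), tp)
  d <- model$dec[[1]]$forward(b, tp)                       # S/16
  d <- model$dec[[2]]$forward(d, tp)                       # S/8
  d <- nn_add_op(d, model$bridges[[3]]$forward(skips[[3]], tp), tp)
  d <- model$dec[[3]]$forward(d, tp)                       # S/4
  d <- nn_add_op(d, model$bridges[[2]]$forward(skips[[2]], tp), tp)
  d <- model$dec[[4]]$forward(d, tp)                       # S/2
  d <- nn_add_op(d, model$bridges[[1]]$forward(skips[[1]], tp), tp)
  h <- nn_lrelu_op(model$head_bn$forward(model$head_up$forward(d, tp), tp), tp, sl)
  logits <- model$head_out$forward(h, tp)
  loss_node <- NULL
  if (!is.null(target)) loss_node <- nn_softmax_ce_op(logits, target, tp)
  list(logits = logits$value, loss = if (is.null(loss_node)) NULL else loss_node$value,
       loss_node = loss_node, logits_node = logits, tape = tp, encoder_sizes = sizes)
}

#' Spatial attention map
#'
#' Aggregates channel information by channel-wise max and average pooling
#' (two `H x W` maps), concatenates them, applies a 3x3 convolution to one
#' channel and a LeakyReLU. This is the attention mechanism used inside each
#' RSAP bridge.
#'
#' @param x `H x W x C` feature array.
#' @param weights Optional `18 x 1` kernel matrix (3x3 kernel over the two
#'   pooled maps, flattened row-index fastest); default He-initialised under
#'   `seed`.
#' @param bias Scalar bias (default 0).
#' @param slope LeakyReLU negative slope.
#' @param seed Seed for the default weights.
#' @return `H x W x 1` attention map.
#' @export
spatial_attention <- function(x, weights = NULL, bias = 0, slope = 0.01, seed = 1) {
  x <- as_image_array(x)
  if (is.null(weights)) weights <- with_seed(seed, he_weight(3, 2, 1))
  mx <- apply(x, c(1, 2), max)
  av <- apply(x, c(1, 2), mean)
  pooled <- array(c(mx, av), dim = c(dim(x)[1], dim(x)[2], 2))
  y <- cpp_conv2d(pooled, weights, bias, 3L, 1L, 1L, 1L)
  ifelse(y > 0, y, slope * y)
}

#' Multi-branch dilated convolution block (functional form)
#'
#' Applies the MDC bottleneck block with freshly initialised weights: an
#' identity branch plus cascaded dilated-convolution branches (dilation
#' rates accumulating along the cascade), each closed by a linear 1x1
#' convolution, all summed. Spatial size is preserved.
#'
#' @param x `H x W x C` feature array.
#' @param dilations Cascade dilation rates.
#' @param slope LeakyReLU negative slope.
#' @param seed Weight seed.
#' @param zero_weights If TRUE all convolution weights are zero, so the
#'   output equals the identity branch (useful for testing).
#' @return `H x W x C` array.
#' @export
mdc_block <- function(x, dilations = c(1, 2, 5), slope = 0.01, seed = 1,
                      zero_weights = FALSE) {
  x <- as_image_array(x)
  c <- dim(x)[3]
  mdc <- with_seed(seed, make_mdc(c, dilations, slope))
  if (zero_weights)
    for (ly in mdc$layers) if (!is.null(ly$w)) ly$w$value[] <- 0
  tp <- nn_tape()
  mdc$forward(nn_node(tp, x), tp)$value
}

#' Global information coding block (functional form)
#'
#' Two strided convolution branches and two max-pooling branches, each
#' reduced to a single channel by a 1x1 convolution and bilinearly upsampled
#' back to the input size, concatenated with the input: the channel count
#' grows by exactly four.
#'
#' @param x `H x W x C` feature array with `H, W >= 6` for the default
#'   branch sizes.
#' @param pool_sizes Max-pool kernel (= stride) sizes.
#' @param conv_specs List of `c(kernel, stride)` pairs.
#' @param slope LeakyReLU negative slope.
#' @param seed Weight seed.
#' @return `H x W x (C+4)` array.
#' @export
gic_block <- function(x, pool_sizes = c(5, 6), conv_specs = list(c(2, 2), c(3, 3)),
                      slope = 0.01, seed = 1) {
  x <- as_image_array(x)
  if (dim(x)[1] < max(pool_sizes) || dim(x)[2] < max(pool_sizes))
    stop("gic_block requires spatial size >= ", max(pool_sizes))
  c <- dim(x)[3]
  gic <- with_seed(seed, make_gic(c, pool_sizes, conv_specs, dim(x)[1], slope))
  tp <- nn_tape()
  gic$forward(nn_node(tp, x), tp)$value
}

#' Number of trainable parameters
#' @param model An [rsap_net()] model.
#' @return Integer parameter count.
#' @export
n_params <- function(model) n_parameters(model$params)

#' Save / load model checkpoints
#'
#' A checkpoint is a single RDS file holding the configuration and all
#' parameter values.
#'
#' @param model An [rsap_net()] model.
#' @param path File path.
#' @return `load_checkpoint` returns a reconstructed model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(config = model$config,
               values = lapply(model$params, function(p) p$value)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- rsap_net(ck$config, seed = 1)
  stopifnot(length(model$params) == length(ck$values))
  for (i in seq_along(ck$values)) model$params[[i]]$value <- ck$values[[i]]
  model
}
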