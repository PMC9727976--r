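# Minimal reverse-mode automatic differentiation over H x W x C arrays,
# backing the segmentation network. A "tape" records nodes in forward order;
# backward() walks it in reverse. Parameters are environments holding value,
# accumulated gradient and an SGD momentum buffer; layer closures capture
# them so gradients accumulate across images (gradient-accumulation
# mini-batching). All heavy lifting (convolutions, pooling) is done by the
# compiled kernels in src/.

nn_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- list()
  tp
}

nn_node <- function(tape, value, backward = NULL) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  n$backward <- backward
  if (!is.null(tape)) tape$nodes[[length(tape$nodes) + 1L]] <- n
  n
}

nn_accum <- function(node, g) {
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

#' Backpropagate through a recorded forward pass
#'
#' Seeds the loss node with gradient 1 and walks the tape in reverse,
#' accumulating gradients into every parameter that contributed. Used
#' together with [nn_forward()] when writing a custom training loop;
#' [train_model()] wraps this.
#'
#' @param tape The tape returned by [nn_forward()].
#' @param loss_node The loss node returned by [nn_forward()].
#' @return Invisibly `NULL`; gradients are accumulated in place.
#' @export
nn_backward <- function(tape, loss_node) {
  loss_node$grad <- 1
  for (i in rev(seq_along(tape$nodes))) {
    n <- tape$nodes[[i]]
    if (!is.null(n$grad) && !is.null(n$backward)) n$backward(n$grad)
  }
  invisible(NULL)
}

nn_param <- function(value) {
  p <- new.env(parent = emptyenv())
  p$value <- value
  p$grad <- NULL
  p$m <- NULL
  p$decay <- TRUE  # subject to weight decay unless flipped off
  p
}

param_accum <- function(p, g) {
  p$grad <- if (is.null(p$grad)) g else p$grad + g
  invisible(NULL)
}

# He fan-in initialisation for a k x k conv, stored as (k*k*cin) x cout
he_weight <- function(k, cin, cout) {
  matrix(rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))), k * k * cin, cout)
}

# ---- layers -----------------------------------------------------------------

nn_conv <- function(cin, cout, k = 3, stride = 1, pad = (k - 1) %/% 2, dil = 1) {
  if (dil > 1) pad <- dil * (k - 1) %/% 2  # "same" padding for odd k
  w <- nn_param(he_weight(k, cin, cout))
  b <- nn_param(rep(0, cout)); b$decay <- FALSE
  layer <- list(w = w, b = b, k = k, stride = stride, pad = pad, dil = dil,
                cin = cin, cout = cout, type = "conv")
  layer$forward <- function(x, tape) {
    xv <- x$value
    y <- cpp_conv2d(xv, w$value, b$value, k, stride, pad, dil)
    nn_node(tape, y, backward = function(g) {
      bw <- cpp_conv2d_bwd(xv, w$value, g, k, stride, pad, dil)
      param_accum(w, bw$gw); param_accum(b, as.numeric(bw$gb))
      nn_accum(x, bw$gx)
    })
  }
  layer
}

# transposed conv, kernel 3 stride 2 pad 1 output-padding 1: doubles H and W
nn_convt <- function(cin, cout, k = 3, stride = 2, pad = 1, opad = 1) {
  w <- nn_param(he_weight(k, cout, cin))  # conv orientation: out -> in
  b <- nn_param(rep(0, cout)); b$decay <- FALSE
  layer <- list(w = w, b = b, k = k, stride = stride, pad = pad, opad = opad,
                cin = cin, cout = cout, type = "convt")
  layer$forward <- function(x, tape) {
    xv <- x$value
    y <- cpp_convt2d(xv, w$value, b$value, k, stride, pad, opad)
    nn_node(tape, y, backward = function(g) {
      bw <- cpp_convt2d_bwd(xv, w$value, g, k, stride, pad)
      param_accum(w, bw$gw); param_accum(b, as.numeric(bw$gb))
      nn_accum(x, bw$gx)
    })
  }
  layer
}

# per-channel normalization over the spatial extent of the current image
# (instance-style statistics: deterministic per image in both training and
# inference, no running averages)
nn_bn <- function(c, eps = 1e-5) {
  gamma <- nn_param(rep(1, c)); gamma$decay <- FALSE
  beta <- nn_param(rep(0, c)); beta$decay <- FALSE
  layer <- list(gamma = gamma, beta = beta, c = c, eps = eps, type = "bn")
  layer$forward <- function(x, tape) {
    xv <- x$value
    d <- dim(xv); np <- d[1] * d[2]; C <- d[3]
    xm <- matrix(xv, np, C)
    mu <- colMeans(xm)
    xc <- xm - rep(mu, each = np)
    istd <- 1 / sqrt(colMeans(xc * xc) + eps)
    xhat <- xc * rep(istd, each = np)
    y <- array(xhat * rep(gamma$value, each = np) + rep(beta$value, each = np), dim = d)
    nn_node(tape, y, backward = function(g) {
      gm <- matrix(g, np, C)
      param_accum(gamma, colSums(gm * xhat))
      param_accum(beta, colSums(gm))
      gh <- gm * rep(gamma$value, each = np)
      m1 <- colMeans(gh)
      m2 <- colMeans(gh * xhat)
      gx <- (gh - rep(m1, each = np) - xhat * rep(m2, each = np)) * rep(istd, each = np)
      nn_accum(x, array(gx, dim = d))
    })
  }
  layer
}

nn_lrelu_op <- function(x, tape, slope = 0.01) {
  xv <- x$value
  pos <- xv > 0
  scale <- slope + (1 - slope) * pos
  y <- xv * scale
  nn_node(tape, y, backward = function(g) {
    nn_accum(x, g * scale)
  })
}

nn_maxpool_op <- function(x, tape, k = 2, s = k) {
  xv <- x$value
  r <- cpp_maxpool(xv, k, s)
  d <- dim(xv)
  nn_node(tape, r$y, backward = function(g) {
    nn_accum(x, cpp_maxpool_bwd(g, r$idx, d[1], d[2], d[3]))
  })
}

nn_add_op <- function(a, b, tape) {
  nn_node(tape, a$value + b$value, backward = function(g) {
    nn_accum(a, g); nn_accum(b, g)
  })
}

# elementwise multiply of a C-channel tensor by a 1-channel map; the map is
# broadcast over channels via column-major recycling (channels outermost)
nn_mul_map_op <- function(x, m, tape) {
  xv <- x$value; mv <- as.vector(m$value)
  d <- dim(xv); np <- d[1] * d[2]
  y <- xv * mv  # recycles the H*W map across channels
  nn_node(tape, y, backward = function(g) {
    nn_accum(x, g * mv)
    gm <- rowSums(matrix(g * xv, np, d[3]))
    nn_accum(m, array(gm, dim = c(d[1], d[2], 1)))
  })
}

nn_concat_op <- function(nodes, tape) {
  vals <- lapply(nodes, function(n) n$value)
  cs <- vapply(vals, function(v) dim(v)[3], integer(1))
  y <- array(unlist(vals), dim = c(dim(vals[[1]])[1], dim(vals[[1]])[2], sum(cs)))
  ends <- cumsum(cs); starts <- c(1, head(ends, -1) + 1)
  nn_node(tape, y, backward = function(g) {
    for (i in seq_along(nodes))
      nn_accum(nodes[[i]], g[, , starts[i]:ends[i], drop = FALSE])
  })
}

# channel-wise max and mean pooling to H x W x 1 maps (spatial attention input)
nn_chanmax_op <- function(x, tape) {
  xv <- x$value
  d <- dim(xv); np <- d[1] * d[2]
  xm <- matrix(xv, np, d[3])
  idx <- max.col(xm, ties.method = "first")
  sel <- cbind(seq_len(np), idx)
  y <- array(xm[sel], dim = c(d[1], d[2], 1))
  nn_node(tape, y, backward = function(g) {
    gx <- matrix(0, np, d[3])
    gx[sel] <- as.vector(g)
    nn_accum(x, array(gx, dim = d))
  })
}

nn_chanmean_op <- function(x, tape) {
  xv <- x$value
  d <- dim(xv); np <- d[1] * d[2]
  y <- array(rowMeans(matrix(xv, np, d[3])), dim = c(d[1], d[2], 1))
  nn_node(tape, y, backward = function(g) {
    nn_accum(x, array(as.vector(g) / d[3], dim = d))
  })
}

# separable bilinear upsampling to (h_out, w_out); adjoint uses the
# transposed interpolation matrices
nn_upsample_op <- function(x, tape, h_out, w_out) {
  xv <- x$value
  Lh <- linear_interp_matrix(dim(xv)[1], h_out)
  Lw <- linear_interp_matrix(dim(xv)[2], w_out)
  C <- dim(xv)[3]
  y <- array(0, dim = c(h_out, w_out, C))
  for (c in seq_len(C)) y[, , c] <- Lh %*% xv[, , c] %*% t(Lw)
  nn_node(tape, y, backward = function(g) {
    gx <- array(0, dim = dim(xv))
    for (c in seq_len(C)) gx[, , c] <- t(Lh) %*% g[, , c] %*% Lw
    nn_accum(x, gx)
  })
}

# three-class softmax cross-entropy, mean over pixels; target is an H x W
# matrix of labels in 0..(C-1)
nn_softmax_ce_op <- function(logits, target, tape) {
  xv <- logits$value
  d <- dim(xv); np <- d[1] * d[2]; C <- d[3]
  if (!all(target %in% 0:(C - 1))) stop("target labels outside class range")
  xm <- matrix(xv, np, C)
  m <- xm[, 1]
  for (c in seq_len(C - 1) + 1L) m <- pmax(m, xm[, c])
  ex <- exp(xm - m)
  se <- rowSums(ex)
  tidx <- cbind(seq_len(np), as.vector(target) + 1L)
  loss <- mean(m + log(se) - xm[tidx])
  nn_node(tape, loss, backward = function(g) {
    soft <- ex / se
    soft[tidx] <- soft[tidx] - 1
    nn_accum(logits, array(soft * (g / np), dim = d))
  })
}

# ---- parameter handling -----------------------------------------------------

collect_params <- function(layers) {
  out <- list()
  for (ly in layers) {
    if (is.null(ly)) next
    for (nm in c("w", "b", "gamma", "beta"))
      if (!is.null(ly[[nm]])) out[[length(out) + 1L]] <- ly[[nm]]
  }
  out
}

sgd_step <- function(params, lr, momentum = 0.9, weight_decay = 0, scale = 1) {
  for (p in params) {
    if (is.null(p$grad)) next
    g <- p$grad * scale
    if (weight_decay > 0 && isTRUE(p$decay)) g <- g + weight_decay * p$value
    p$m <- if (is.null(p$m)) g else momentum * p$m + g
    p$value <- p$value - lr * p$m
    p$grad <- NULL
  }
  invisible(NULL)
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

n_parameters <- function(params) sum(vapply(params, function(p) length(p$value), numeric(1)))
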