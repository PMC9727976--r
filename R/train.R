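# Training and inference. Optimisation follows the reference protocol:
# stochastic gradient descent with learning rate 0.001, momentum 0.9 and
# weight decay 0.0005, minimising the three-class cross-entropy. Gradients
# are accumulated over `batch_size` images between parameter updates.

# map 0..255 intensities to the symmetric range the network consumes
prepare_input <- function(image) image / 127.5 - 1

#' Train an RSAP-Net on a list of image/mask pairs
#'
#' @param model An [rsap_net()] model (modified in place).
#' @param images List of `S x S x 3` arrays with intensities in `[0, 255]`.
#' @param masks List of `S x S` label matrices over `{0, 1, 2}`.
#' @param epochs Number of passes over the data.
#' @param lr Learning rate (default 0.001).
#' @param momentum SGD momentum (default 0.9).
#' @param weight_decay L2 penalty on convolution weights (default 0.0005).
#' @param batch_size Images per parameter update (gradient accumulation).
#' @param seed Seed controlling the per-epoch shuffling.
#' @param verbose Print the mean loss after each epoch.
#' @return Invisibly, the numeric vector of mean per-epoch losses (also
#'   stored as `model$loss_history`).
#' @export
train_model <- function(model, images, masks, epochs = 10, lr = 0.001,
                        momentum = 0.9, weight_decay = 5e-4, batch_size = 1,
                        seed = 1, verbose = FALSE) {
  stopifnot(length(images) == length(masks))
  n <- length(images)
  xs <- lapply(images, prepare_input)
  losses <- numeric(epochs)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      pending <- 0L
      for (ii in seq_along(ord)) {
        i <- ord[ii]
        fw <- nn_forward(model, xs[[i]], target = masks[[i]])
        ep_loss <- ep_loss + fw$loss
        nn_backward(fw$tape, fw$loss_node)
        pending <- pending + 1L
        if (pending == batch_size || ii == n) {
          sgd_step(model$params, lr, momentum, weight_decay, scale = 1 / pending)
          pending <- 0L
        }
      }
      losses[ep] <- ep_loss / n
      if (verbose) message(sprintf("epoch %d/%d  mean loss %.4f", ep, epochs, losses[ep]))
    }
  })
  model$loss_history <- c(model$loss_history, losses)
  invisible(losses)
}

#' Predict a label mask for one image
#'
#' Runs a forward pass and takes the per-pixel argmax over the three class
#' logits.
#'
#' @param model A trained [rsap_net()] model.
#' @param image `S x S x 3` array with intensities in `[0, 255]`.
#' @return `S x S` integer matrix over `{0, 1, 2}`.
#' @export
predict_mask <- function(model, image) {
  fw <- nn_forward(model, prepare_input(image))
  lg <- fw$logits
  cls <- max.col(matrix(lg, nrow = dim(lg)[1] * dim(lg)[2], ncol = dim(lg)[3]),
                 ties.method = "first") - 1L
  matrix(cls, dim(lg)[1], dim(lg)[2])
}
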