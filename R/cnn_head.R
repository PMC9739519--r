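# Baseline classifier heads for the ablation ladder: a small convolutional
# classifier applied directly to scalogram stacks, and a one-hidden-layer
# softmax head applied to extracted feature vectors (the "fully connected
# layers of a CNN" the feature-extraction experiments feed).

#' Train a small CNN classifier on scalogram stacks
#'
#' One convolutional block (3x3 kernels, ReLU, 2x2 max pooling) followed by
#' a dense softmax over the four quadrants; trained with minibatch Adam.
#' This is the baseline head of the ablation ladder, not part of the
#' proposed ensemble.
#'
#' @param x Array `H x W x C x n` of image stacks.
#' @param labels Character quadrant labels.
#' @param filters,epochs,batch_size,lr Training controls.
#' @param seed Seed (initialization + shuffling).
#' @return An object of class `cnn_head`.
#' @export
train_cnn_head <- function(x, labels, filters = 8L, epochs = 15L,
                           batch_size = 32L, lr = 1e-3, seed = 1L) {
  classes <- quadrant_levels()
  check_training_labels(labels, classes)
  y <- match(labels, classes)
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]; n <- d[4]
  k <- 3L
  D <- (H / 2) * (W / 2) * filters
  withr::with_seed(seed, {
    p <- list(W1 = matrix(rnorm(k * k * C * filters,
                                sd = sqrt(2 / (k * k * C))),
                          k * k * C, filters),
              b1 = numeric(filters),
              W2 = matrix(rnorm(D * length(classes), sd = sqrt(1 / D)),
                          D, length(classes)),
              b2 = numeric(length(classes)))
    opt <- adam_init(p)
    bs <- min(batch_size, n)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1, n)]
        xb <- batch4d_to_mat(x[, , , idx, drop = FALSE])
        B <- length(idx)
        cv <- conv_fw(xb, H, W, B, p$W1, p$b1, k)
        mask <- cv$out > 0
        a <- cv$out * mask
        pool <- maxpool2_fw(a, H, W, B)
        flat <- mat_to_flat(pool$values, H / 2, W / 2, B)
        logits <- sweep(flat %*% p$W2, 2, p$b2, "+")
        sx <- softmax_xent(logits, y[idx])
        g <- list(W1 = NULL, b1 = NULL,
                  W2 = crossprod(flat, sx$dlogits),
                  b2 = colSums(sx$dlogits))
        dflat <- sx$dlogits %*% t(p$W2)
        dpool <- flat_to_mat(dflat, H / 2, W / 2, B, filters)
        da <- pool_scatter(dpool, pool$idx, H * W * B) * mask
        cb <- conv_bw(da, cv, p$W1, H, W, B, C, k)
        g$W1 <- cb$dW; g$b1 <- cb$db
        st <- adam_step(opt, p, g, lr = lr)
        p <- st$params; opt <- st$state
      }
    }
  })
  structure(list(params = p, classes = classes, H = H, W = W, C = C,
                 filters = filters, k = k), class = "cnn_head")
}

#' @export
predict.cnn_head <- function(object, newdata, ...) {
  p <- object$params
  d <- dim(newdata)
  B <- if (length(d) == 4) d[4] else 1
  xb <- batch4d_to_mat(newdata)
  cv <- conv_fw(xb, object$H, object$W, B, p$W1, p$b1, object$k)
  a <- cv$out * (cv$out > 0)
  pool <- maxpool2_fw(a, object$H, object$W, B)
  flat <- mat_to_flat(pool$values, object$H / 2, object$W / 2, B)
  logits <- sweep(flat %*% p$W2, 2, p$b2, "+")
  object$classes[max.col(logits, ties.method = "first")]
}

#' Train a dense softmax head on feature vectors
#'
#' One hidden ReLU layer plus softmax, full-batch Adam (deterministic under
#' seed). Used by the ablation ladder's feature-extraction + CNN-head rows.
#'
#' @param features `n x d` matrix.
#' @param labels Character quadrant labels.
#' @param hidden,epochs,lr Training controls.
#' @param seed Seed.
#' @return An object of class `dense_head`.
#' @export
train_dense_head <- function(features, labels, hidden = 32L, epochs = 60L,
                             lr = 1e-2, seed = 1L) {
  classes <- quadrant_levels()
  check_training_labels(labels, classes)
  y <- match(labels, classes)
  X <- as.matrix(features)
  d <- ncol(X)
  withr::with_seed(seed, {
    p <- list(W1 = matrix(rnorm(d * hidden, sd = sqrt(2 / d)), d, hidden),
              b1 = numeric(hidden),
              W2 = matrix(rnorm(hidden * length(classes),
                                sd = sqrt(1 / hidden)),
                          hidden, length(classes)),
              b2 = numeric(length(classes)))
    opt <- adam_init(p)
    for (ep in seq_len(epochs)) {
      z1 <- sweep(X %*% p$W1, 2, p$b1, "+")
      a1 <- z1 * (z1 > 0)
      logits <- sweep(a1 %*% p$W2, 2, p$b2, "+")
      sx <- softmax_xent(logits, y)
      da1 <- (sx$dlogits %*% t(p$W2)) * (z1 > 0)
      g <- list(W1 = crossprod(X, da1), b1 = colSums(da1),
                W2 = crossprod(a1, sx$dlogits), b2 = colSums(sx$dlogits))
      st <- adam_step(opt, p, g, lr = lr)
      p <- st$params; opt <- st$state
    }
  })
  structure(list(params = p, classes = classes), class = "dense_head")
}

#' @export
predict.dense_head <- function(object, newdata, ...) {
  p <- object$params
  X <- as.matrix(newdata)
  z1 <- sweep(X %*% p$W1, 2, p$b1, "+")
  a1 <- z1 * (z1 > 0)
  logits <- sweep(a1 %*% p$W2, 2, p$b2, "+")
  object$classes[max.col(logits, ties.method = "first")]
}
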