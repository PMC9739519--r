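#' Stacked convolutional autoencoder configuration
#'
#' The encoder is a stack of convolutional blocks (convolution, batch
#' normalization, ReLU, 2x2 max pooling with recorded argmax indices,
#' dropout) with 15x15, 9x9 and 3x3 kernels by default, followed by a
#' flatten and an affine projection to the bottleneck feature vector. The
#' decoder mirrors the encoder: affine expansion, then per block max
#' unpooling (to the recorded positions), transposed convolution, batch
#' normalization, ReLU and dropout; the final reconstruction layer is
#' linear. Training minimizes mean squared reconstruction error plus
#' `lambda` times the squared Frobenius norm of the bottleneck-input
#' Jacobian (the contractive penalty).
#'
#' @param input_planes Number of image planes (default 17 = 14 EEG + 2 ECG +
#'   1 GSR channel scalograms).
#' @param size Image `(H, W)`; both must be divisible by `2^length(kernels)`.
#' @param kernels Odd kernel sizes, one per encoder block.
#' @param filters Filter counts per block.
#' @param bottleneck Bottleneck dimension; must be smaller than the
#'   flattened input size (compression).
#' @param lambda Contractive penalty weight, `>= 0`.
#' @param dropout Dropout rate in `[0, 1)`.
#' @param batchnorm Use batch normalization (default `TRUE`).
#' @param epochs,batch_size,lr Adam training schedule.
#' @param seed Seed controlling initialization, shuffling, dropout and the
#'   penalty probes.
#' @return An object of class `sae_config`.
#' @export
sae_config <- function(input_planes = 17L, size = c(64L, 64L),
                       kernels = c(15L, 9L, 3L), filters = c(16L, 32L, 64L),
                       bottleneck = 128L, lambda = 1e-4, dropout = 0.1,
                       batchnorm = TRUE, epochs = 50L, batch_size = 32L,
                       lr = 1e-3, seed = 1L) {
  stopifnot(length(kernels) == length(filters), length(kernels) >= 1)
  if (any(kernels %% 2 == 0)) stop("sae_config: kernel sizes must be odd")
  if (lambda < 0) stop("sae_config: lambda must be >= 0")
  nb <- length(kernels)
  if (any(size %% 2^nb != 0))
    stop("sae_config: image size ", paste(size, collapse = "x"),
         " must be divisible by 2^", nb)
  d_in <- prod(size) * input_planes
  if (bottleneck >= d_in)
    stop("sae_config: bottleneck (", bottleneck,
         ") must be smaller than the flattened input (", d_in,
         "); the bottleneck is a compression")
  structure(list(input_planes = as.integer(input_planes),
                 size = as.integer(size), kernels = as.integer(kernels),
                 filters = as.integer(filters),
                 bottleneck = as.integer(bottleneck), lambda = lambda,
                 dropout = dropout, batchnorm = isTRUE(batchnorm),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 seed = as.integer(seed)),
            class = "sae_config")
}

sae_dims <- function(cfg) {
  nb <- length(cfg$kernels)
  Hf <- cfg$size[1] / 2^nb; Wf <- cfg$size[2] / 2^nb
  list(nb = nb, Hf = Hf, Wf = Wf, flat = Hf * Wf * cfg$filters[nb])
}

#' Initialize autoencoder parameters
#'
#' He-scaled random weights, drawn deterministically from `cfg$seed`. The
#' result carries `trained = FALSE` until [sae_train()] has run.
#'
#' @param cfg An [sae_config()].
#' @return An object of class `sae_model`.
#' @export
sae_init <- function(cfg) {
  dm <- sae_dims(cfg)
  withr::with_seed(cfg$seed, {
    c_in <- cfg$input_planes
    enc <- list(); dec <- list(); stats <- list(enc = list(), dec = list())
    for (i in seq_len(dm$nb)) {
      k <- cfg$kernels[i]; f <- cfg$filters[i]
      enc[[i]] <- list(
        W = matrix(rnorm(k * k * c_in * f, sd = sqrt(2 / (k * k * c_in))),
                   k * k * c_in, f),
        b = numeric(f), gamma = rep(1, f), beta = numeric(f))
      stats$enc[[i]] <- list(mean = numeric(f), var = rep(1, f))
      c_in <- f
    }
    proj <- list(
      W = matrix(rnorm(dm$flat * cfg$bottleneck, sd = sqrt(1 / dm$flat)),
                 dm$flat, cfg$bottleneck),
      b = numeric(cfg$bottleneck))
    dproj <- list(
      W = matrix(rnorm(cfg$bottleneck * dm$flat,
                       sd = sqrt(1 / cfg$bottleneck)),
                 cfg$bottleneck, dm$flat),
      b = numeric(dm$flat))
    for (i in seq_len(dm$nb)) {
      k <- cfg$kernels[i]; f_in <- cfg$filters[i]
      f_out <- if (i > 1) cfg$filters[i - 1] else cfg$input_planes
      dec[[i]] <- list(
        W = matrix(rnorm(k * k * f_in * f_out, sd = sqrt(2 / (k * k * f_in))),
                   k * k * f_in, f_out),
        b = numeric(f_out), gamma = rep(1, f_out), beta = numeric(f_out))
      stats$dec[[i]] <- list(mean = numeric(f_out), var = rep(1, f_out))
    }
    structure(list(config = cfg,
                   weights = list(enc = enc, proj = proj, dproj = dproj,
                                  dec = dec),
                   bn_stats = stats, trained = FALSE,
                   loss_history = numeric(0)),
              class = "sae_model")
  })
}

#' @export
print.sae_model <- function(x, ...) {
  cfg <- x$config
  cat("<sae_model>", length(cfg$kernels), "conv blocks (kernels",
      paste(cfg$kernels, collapse = "/"), ", filters",
      paste(cfg$filters, collapse = "/"), "), bottleneck", cfg$bottleneck,
      if (x$trained) sprintf("- trained, final loss %.4g",
                             tail(x$loss_history, 1)) else "- untrained",
      "\n")
  invisible(x)
}

# Encoder forward. x_mat is (H*W*B) x C. Returns bottleneck (B x dim),
# per-block caches, and (in training mode) updated running BN stats.
enc_forward <- function(net, x_mat, B, training = FALSE, drop_masks = NULL) {
  cfg <- net$config
  H <- cfg$size[1]; W <- cfg$size[2]
  caches <- list()
  stats <- net$bn_stats
  x <- x_mat
  for (i in seq_along(cfg$kernels)) {
    p <- net$weights$enc[[i]]
    cv <- conv_fw(x, H, W, B, p$W, p$b, cfg$kernels[i])
    c_in <- ncol(x)
    y <- cv$out
    bn <- NULL
    if (cfg$batchnorm) {
      bn <- bn_fw(y, p$gamma, p$beta, training,
                  stats$enc[[i]]$mean, stats$enc[[i]]$var)
      if (training)
        stats$enc[[i]] <- list(mean = bn$run_mean, var = bn$run_var)
      y <- bn$out
    }
    relu_mask <- y > 0
    y <- y * relu_mask
    pool <- maxpool2_fw(y, H, W, B)
    Hp <- H / 2; Wp <- W / 2
    drop <- NULL
    if (training && cfg$dropout > 0) {
      drop <- if (!is.null(drop_masks)) drop_masks[[i]] else
        matrix(runif(length(pool$values)) >= cfg$dropout,
               nrow(pool$values)) / (1 - cfg$dropout)
      pool$values <- pool$values * drop
    }
    caches[[i]] <- list(conv = list(xf = cv$xf, kf = cv$kf, P = cv$P), c_in = c_in, bn = bn,
                        relu_mask = relu_mask, pool_idx = pool$idx,
                        n_pre_pool = H * W * B, H = H, W = W,
                        drop = drop)
    x <- pool$values
    H <- Hp; W <- Wp
  }
  flat <- mat_to_flat(x, H, W, B)
  z <- sweep(flat %*% net$weights$proj$W, 2, net$weights$proj$b, "+")
  list(z = z, flat = flat, caches = caches, Hf = H, Wf = W, B = B,
       bn_stats = stats)
}

# Encoder backward: gradient of a scalar loss wrt bottleneck (dz, B x dim)
# propagated to all encoder parameters and to the input.
enc_backward <- function(net, fw, dz, training = TRUE) {
  cfg <- net$config
  g <- list(enc = vector("list", length(cfg$kernels)),
            proj = list(W = crossprod(fw$flat, dz), b = colSums(dz)))
  dflat <- dz %*% t(net$weights$proj$W)
  H <- fw$Hf; W <- fw$Wf; B <- fw$B
  dx <- flat_to_mat(dflat, H, W, B, cfg$filters[length(cfg$filters)])
  for (i in rev(seq_along(cfg$kernels))) {
    cc <- fw$caches[[i]]
    if (!is.null(cc$drop)) dx <- dx * cc$drop
    dy <- pool_scatter(dx, cc$pool_idx, cc$n_pre_pool)
    dy <- dy * cc$relu_mask
    gi <- list()
    if (cfg$batchnorm) {
      bb <- bn_bw(dy, cc$bn, net$weights$enc[[i]]$gamma, training)
      dy <- bb$dx
      gi$gamma <- bb$dgamma; gi$beta <- bb$dbeta
    } else {
      gi$gamma <- numeric(length(net$weights$enc[[i]]$gamma))
      gi$beta <- numeric(length(net$weights$enc[[i]]$beta))
    }
    cb <- conv_bw(dy, cc$conv, net$weights$enc[[i]]$W, cc$H, cc$W, B,
                  cc$c_in, cfg$kernels[i])
    gi$W <- cb$dW; gi$b <- cb$db
    g$enc[[i]] <- gi
    dx <- cb$dx
    H <- cc$H; W <- cc$W
  }
  list(grads = g, dx = dx)
}

# Decoder forward from bottleneck z, reusing the encoder's pooling indices.
dec_forward <- function(net, z, enc_fw, training = FALSE, drop_masks = NULL) {
  cfg <- net$config
  nb <- length(cfg$kernels)
  stats <- net$bn_stats
  flat <- sweep(z %*% net$weights$dproj$W, 2, net$weights$dproj$b, "+")
  B <- enc_fw$B
  x <- flat_to_mat(flat, enc_fw$Hf, enc_fw$Wf, B, cfg$filters[nb])
  caches <- list()
  for (i in nb:1) {
    cc <- fwcc <- enc_fw$caches[[i]]
    big <- pool_scatter(x, cc$pool_idx, cc$n_pre_pool)
    p <- net$weights$dec[[i]]
    cv <- conv_fw(big, cc$H, cc$W, B, p$W, p$b, cfg$kernels[i])
    y <- cv$out
    bn <- NULL; relu_mask <- NULL; drop <- NULL
    if (i > 1) {
      if (cfg$batchnorm) {
        bn <- bn_fw(y, p$gamma, p$beta, training,
                    stats$dec[[i]]$mean, stats$dec[[i]]$var)
        if (training)
          stats$dec[[i]] <- list(mean = bn$run_mean, var = bn$run_var)
        y <- bn$out
      }
      relu_mask <- y > 0
      y <- y * relu_mask
      if (training && cfg$dropout > 0) {
        drop <- if (!is.null(drop_masks)) drop_masks[[i]] else
          matrix(runif(length(y)) >= cfg$dropout, nrow(y)) /
            (1 - cfg$dropout)
        y <- y * drop
      }
    }
    caches[[i]] <- list(conv = list(xf = cv$xf, kf = cv$kf, P = cv$P), c_in = ncol(big), bn = bn,
                        relu_mask = relu_mask, drop = drop,
                        pool_idx = cc$pool_idx, n_small = nrow(x),
                        H = cc$H, W = cc$W)
    x <- y
  }
  list(xhat = x, caches = caches, bn_stats = stats, flat_dims = enc_fw)
}

dec_backward <- function(net, dec_fwd, dxhat, training = TRUE) {
  cfg <- net$config
  nb <- length(cfg$kernels)
  g <- list(dec = vector("list", nb))
  dy <- dxhat
  B <- dec_fwd$flat_dims$B
  for (i in seq_len(nb)) {
    cc <- dec_fwd$caches[[i]]
    gi <- list()
    if (i > 1) {
      if (!is.null(cc$drop)) dy <- dy * cc$drop
      dy <- dy * cc$relu_mask
      if (cfg$batchnorm) {
        bb <- bn_bw(dy, cc$bn, net$weights$dec[[i]]$gamma, training)
        dy <- bb$dx
        gi$gamma <- bb$dgamma; gi$beta <- bb$dbeta
      }
    }
    if (is.null(gi$gamma)) {
      gi$gamma <- numeric(length(net$weights$dec[[i]]$gamma))
      gi$beta <- numeric(length(net$weights$dec[[i]]$beta))
    }
    cb <- conv_bw(dy, cc$conv, net$weights$dec[[i]]$W, cc$H, cc$W, B,
                  cc$c_in, cfg$kernels[i])
    gi$W <- cb$dW; gi$b <- cb$db
    g$dec[[i]] <- gi
    dy <- pool_gather(cb$dx, cc$pool_idx)
  }
  dm <- dec_fwd$flat_dims
  dflat <- mat_to_flat(dy, dm$Hf, dm$Wf, B)
  # dproj$W needs the bottleneck activations; the caller fills it in
  g$dproj <- list(W = NULL, b = colSums(dflat))
  list(grads = g, dflat = dflat)
}

as_batch_mat <- function(x) {
  # accept H x W x C x B array or an (H*W*B) x C matrix plus dims
  stopifnot(length(dim(x)) == 4)
  list(mat = batch4d_to_mat(x), B = dim(x)[4])
}

#' Encode scalogram stacks to bottleneck feature vectors
#'
#' Inference mode: dropout off, batch normalization uses running statistics,
#' so the result is deterministic and independent of batch composition.
#'
#' @param model An `sae_model`.
#' @param x Array `H x W x C x B` of image stacks.
#' @param keep_cache Also return the forward caches (pooling indices),
#'   needed to run [sae_decode()].
#' @return `B x bottleneck` matrix of features (with the forward cache as
#'   attribute `"cache"` when `keep_cache`).
#' @export
sae_encode <- function(model, x, keep_cache = FALSE) {
  stopifnot(inherits(model, "sae_model"))
  bm <- as_batch_mat(check_sae_input(model, x))
  fw <- enc_forward(model, bm$mat, bm$B, training = FALSE)
  z <- fw$z
  if (keep_cache) attr(z, "cache") <- fw
  z
}

check_sae_input <- function(model, x) {
  cfg <- model$config
  d <- dim(x)
  if (length(d) == 3) { dim(x) <- c(d, 1L); d <- dim(x) }
  if (d[1] != cfg$size[1] || d[2] != cfg$size[2] || d[3] != cfg$input_planes)
    stop("sae: input shape ", paste(d[1:3], collapse = "x"),
         " does not match configured ",
         paste(c(cfg$size, cfg$input_planes), collapse = "x"))
  x
}

#' Decode bottleneck features back to image stacks
#'
#' Requires the forward cache of the matching [sae_encode()] call: max
#' unpooling routes values to the argmax positions recorded by the encoder.
#'
#' @param model An `sae_model`.
#' @param z `B x bottleneck` feature matrix.
#' @param cache Forward cache from `sae_encode(..., keep_cache = TRUE)`.
#' @return Array `H x W x C x B` of reconstructions.
#' @export
sae_decode <- function(model, z, cache = attr(z, "cache")) {
  stopifnot(inherits(model, "sae_model"))
  if (is.null(cache))
    stop("sae_decode: no forward cache; run sae_encode(x, keep_cache = TRUE)",
         " on the matching input first (unpooling needs its argmax indices)")
  df <- dec_forward(model, z, cache, training = FALSE)
  mat_to_batch4d(df$xhat, model$config$size[1], model$config$size[2], cache$B)
}

#' Full autoencoder forward pass (inference)
#'
#' @param model An `sae_model`.
#' @param x Array `H x W x C x B`.
#' @return List with `xhat` (same shape as `x`) and `z` (bottleneck matrix).
#' @export
sae_reconstruct <- function(model, x) {
  z <- sae_encode(model, x, keep_cache = TRUE)
  xhat <- sae_decode(model, z)
  list(xhat = xhat, z = `attr<-`(z, "cache", NULL))
}

#' Exact bottleneck-input Jacobian of the encoder
#'
#' Reverse-mode accumulation, one backward sweep per bottleneck unit, in
#' inference mode. Quadratic in network size: intended for small networks
#' and for validating the stochastic penalty estimator.
#'
#' @param model An `sae_model`.
#' @param x A single image stack, array `H x W x C` (or `H x W x C x 1`).
#' @return Matrix `bottleneck x (H*W*C)`; input coordinates are ordered
#'   row, column, then plane.
#' @export
encoder_jacobian <- function(model, x) {
  x <- check_sae_input(model, x)
  bm <- as_batch_mat(x)
  fw <- enc_forward(model, bm$mat, 1L, training = FALSE)
  nb <- model$config$bottleneck
  J <- matrix(0, nb, length(x))
  for (u in seq_len(nb)) {
    dz <- matrix(0, 1, nb); dz[1, u] <- 1
    J[u, ] <- as.vector(enc_backward(model, fw, dz, training = FALSE)$dx)
  }
  J
}

#' Contractive autoencoder loss
#'
#' `L = mean((x - xhat)^2) + lambda * mean_b ||d z_b / d x_b||_F^2`: squared
#' reconstruction error plus the contractive penalty, the squared Frobenius
#' norm of the bottleneck-input Jacobian averaged over the batch. With
#' `lambda = 0` this is exactly the MSE. The penalty here is the exact
#' Jacobian norm (see [encoder_jacobian()]); training uses a stochastic
#' finite-difference estimator of the same quantity for large networks.
#'
#' @param model An `sae_model`.
#' @param x Array `H x W x C x B` of inputs.
#' @param xhat Reconstructions; computed by [sae_reconstruct()] if missing.
#' @param lambda Penalty weight; defaults to the configured value.
#' @return Scalar loss; components as attributes `"mse"` and `"penalty"`.
#' @export
contractive_loss <- function(model, x, xhat = NULL, lambda = NULL) {
  if (is.null(lambda)) lambda <- model$config$lambda
  if (lambda < 0) stop("contractive_loss: lambda must be >= 0")
  x <- check_sae_input(model, x)
  if (is.null(xhat)) xhat <- sae_reconstruct(model, x)$xhat
  stopifnot(all(dim(xhat) == dim(x)))
  mse <- mean((x - xhat)^2)
  pen <- 0
  if (lambda > 0) {
    B <- dim(x)[4]
    pen <- mean(vapply(seq_len(B), function(b)
      sum(encoder_jacobian(model, x[, , , b, drop = FALSE])^2), numeric(1)))
  }
  structure(mse + lambda * pen, mse = mse, penalty = pen)
}

#' Stochastic estimate of the contractive penalty
#'
#' Hutchinson-style probe: for Gaussian `v`, `E ||J v||^2 = ||J||_F^2`; the
#' directional derivative `J v` is approximated by the finite difference
#' `(z(x + eps v) - z(x)) / eps`. This is the estimator used inside
#' [sae_train()]; its agreement with the exact Jacobian norm is testable on
#' small networks.
#'
#' @param model An `sae_model`.
#' @param x Array `H x W x C x B`.
#' @param n_probes Number of random probes to average.
#' @param eps Finite-difference step.
#' @param seed Probe seed.
#' @return Scalar estimate of the batch-mean squared Jacobian norm.
#' @export
contractive_penalty_estimate <- function(model, x, n_probes = 50,
                                         eps = 1e-4, seed = 1L) {
  x <- check_sae_input(model, x)
  bm <- as_batch_mat(x)
  z0 <- enc_forward(model, bm$mat, bm$B, training = FALSE)$z
  withr::with_seed(seed, {
    mean(vapply(seq_len(n_probes), function(i) {
      v <- matrix(rnorm(length(bm$mat)), nrow(bm$mat))
      z1 <- enc_forward(model, bm$mat + eps * v, bm$B, training = FALSE)$z
      mean(rowSums(((z1 - z0) / eps)^2))
    }, numeric(1)))
  })
}

#' Train the stacked autoencoder
#'
#' Unsupervised: minimizes reconstruction MSE plus the contractive penalty
#' with Adam on shuffled minibatches. No label information is used. With a
#' fixed config seed the loss history is reproducible run to run.
#'
#' @param cfg An [sae_config()].
#' @param x Training images, array `H x W x C x n` (a `segment_scalograms()`
#'   list is also accepted).
#' @param verbose Print per-epoch loss.
#' @return A trained `sae_model` with `loss_history` (per-epoch mean loss).
#' @export
sae_train <- function(cfg, x, verbose = FALSE) {
  stopifnot(inherits(cfg, "sae_config"))
  if (is.list(x) && !is.null(x$x)) x <- x$x
  net <- sae_init(cfg)
  x <- check_sae_input(net, x)
  n <- dim(x)[4]
  if (n < 1) stop("sae_train: no training images")
  bs <- min(cfg$batch_size, n)
  history <- numeric(cfg$epochs)
  opt <- adam_init(net$weights)
  withr::with_seed(cfg$seed + 1L, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; n_b <- 0
      for (start in seq(1, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1, n)]
        xb <- x[, , , idx, drop = FALSE]
        bm <- as_batch_mat(xb)
        B <- bm$B
        efw <- enc_forward(net, bm$mat, B, training = TRUE)
        net$bn_stats <- efw$bn_stats
        dfw <- dec_forward(net, efw$z, efw, training = TRUE)
        net$bn_stats <- dfw$bn_stats
        resid <- dfw$xhat - bm$mat
        n_el <- length(bm$mat)
        recon <- sum(resid^2) / n_el
        loss <- recon

        dxhat <- 2 * resid / n_el
        dbw <- dec_backward(net, dfw, dxhat)
        grads <- list(enc = NULL, proj = NULL, dproj = dbw$grads$dproj,
                      dec = dbw$grads$dec)
        grads$dproj$W <- crossprod(efw$z, dbw$dflat)
        dz <- dbw$dflat %*% t(net$weights$dproj$W)

        if (cfg$lambda > 0) {
          # one-probe finite-difference estimate of the contractive term,
          # differentiated through both encoder passes
          eps_c <- 1e-3
          v <- matrix(rnorm(length(bm$mat)), nrow(bm$mat))
          drop_masks <- lapply(efw$caches, `[[`, "drop")
          efw2 <- enc_forward(net, bm$mat + eps_c * v, B, training = TRUE,
                              drop_masks = drop_masks)
          dzdiff <- efw2$z - efw$z
          pen <- mean(rowSums((dzdiff / eps_c)^2))
          loss <- loss + cfg$lambda * pen
          dpen <- 2 * cfg$lambda * dzdiff / (eps_c^2 * B)
          eb2 <- enc_backward(net, efw2, dpen)
          eb1 <- enc_backward(net, efw, dz - dpen)
          grads$enc <- merge_grads(eb1$grads$enc, eb2$grads$enc)
          grads$proj <- merge_grads(eb1$grads$proj, eb2$grads$proj)
        } else {
          eb1 <- enc_backward(net, efw, dz)
          grads$enc <- eb1$grads$enc
          grads$proj <- eb1$grads$proj
        }

        if (!is.finite(loss))
          stop("sae_train: non-finite loss at epoch ", ep, ", batch ",
               n_b + 1, " (learning rate ", cfg$lr,
               "); lower the learning rate or check the inputs")
        st <- adam_step(opt, net$weights, grads, lr = cfg$lr)
        net$weights <- st$params
        opt <- st$state
        ep_loss <- ep_loss + loss; n_b <- n_b + 1
      }
      history[ep] <- ep_loss / n_b
      if (verbose)
        message(sprintf("epoch %3d/%d  loss %.6f", ep, cfg$epochs,
                        history[ep]))
    }
  })
  net$loss_history <- history
  net$trained <- TRUE
  net
}

merge_grads <- function(a, b) {
  if (is.list(a)) {
    for (nm in seq_along(a)) a[[nm]] <- merge_grads(a[[nm]], b[[nm]])
    a
  } else a + b
}

#' Extract bottleneck feature vectors from a trained autoencoder
#'
#' Order-preserving, deterministic, and independent of batching (inference
#' mode throughout).
#'
#' @param model A trained `sae_model`.
#' @param x Array `H x W x C x n` or a `segment_scalograms()` list.
#' @param batch_size Images encoded per pass.
#' @return `n x bottleneck` feature matrix.
#' @export
extract_features <- function(model, x, batch_size = 64L) {
  stopifnot(inherits(model, "sae_model"))
  if (!isTRUE(model$trained))
    stop("extract_features: model is untrained; run sae_train() first")
  if (is.list(x) && !is.null(x$x)) x <- x$x
  x <- check_sae_input(model, x)
  n <- dim(x)[4]
  out <- matrix(0, n, model$config$bottleneck)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    out[idx, ] <- sae_encode(model, x[, , , idx, drop = FALSE])
  }
  out
}
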