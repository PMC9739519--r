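# Small neural-network toolkit: convolution via im2col + BLAS GEMM, batch
# normalization, ReLU, 2x2 max pooling with recorded argmax indices,
# inverted dropout, dense layers, softmax cross-entropy and Adam. Feature
# maps are (H*W*B) x C matrices (see src/conv_ops.cpp for the layout); the
# flattened per-image representation is B x (H*W*C).

batch4d_to_mat <- function(x) {
  d <- dim(x)  # H, W, C, B
  m <- aperm(x, c(1, 2, 4, 3))
  dim(m) <- c(d[1] * d[2] * d[4], d[3])
  m
}

mat_to_batch4d <- function(m, H, W, B) {
  C <- ncol(m)
  dim(m) <- c(H, W, B, C)
  aperm(m, c(1, 2, 4, 3))
}

mat_to_flat <- function(m, H, W, B) {
  C <- ncol(m)
  dim(m) <- c(H * W, B, C)
  m <- aperm(m, c(1, 3, 2))
  dim(m) <- c(H * W * C, B)
  t(m)
}

flat_to_mat <- function(f, H, W, B, C) {
  m <- t(f)
  dim(m) <- c(H * W, C, B)
  m <- aperm(m, c(1, 3, 2))
  dim(m) <- c(H * W * B, C)
  m
}

# ---- FFT-based "same" convolution ----------------------------------------
# Linear convolution realized as circular convolution on a zero-padded
# P x P grid, P >= H + k - 1. Feature maps stay small at these sizes, so
# working in the Fourier domain avoids the enormous im2col patch matrices;
# the im2col route (src/conv_ops.cpp) is retained as conv_fw_ref for
# cross-checking.

# 2-D FFT of every P x P slice of a P x P x M array
fft2_stack <- function(a, inverse = FALSE) {
  d <- dim(a)
  f1 <- stats::mvfft(matrix(a, d[1], d[2] * d[3]), inverse = inverse)
  dim(f1) <- d
  f1 <- aperm(f1, c(2, 1, 3))
  f2 <- stats::mvfft(matrix(f1, d[2], d[1] * d[3]), inverse = inverse)
  dim(f2) <- c(d[2], d[1], d[3])
  out <- aperm(f2, c(2, 1, 3))
  if (inverse) out / (d[1] * d[2]) else out
}

conv_pad_fft <- function(x, H, W, B, P, off) {
  # x: (H*W*B) x C feature-map matrix -> FFT of zero-padded slices,
  # returned as (P*P) x (B*C) complex matrix (b fastest within slice index)
  C <- ncol(x)
  xp <- array(0, c(P, P, B * C))
  dim(x) <- c(H, W, B * C)      # (h, w, b) row order, channels as slices
  xp[off + seq_len(H), off + seq_len(W), ] <- x
  f <- fft2_stack(xp)
  dim(f) <- c(P * P, B * C)
  f
}

kernel_fft <- function(Wmat, k, C, Fn, P) {
  kp <- array(0, c(P, P, C * Fn))
  kp[seq_len(k), seq_len(k), ] <- array(Wmat, c(k, k, C, Fn))
  f <- fft2_stack(kp)
  dim(f) <- c(P * P, C, Fn)
  f
}

# FFT of the spatially flipped kernel from the unflipped one: for real K,
# flip about the origin conjugates the spectrum up to a linear phase
kernel_fft_flip <- function(kf, k, P) {
  w <- exp(-2i * pi * (k - 1) * (0:(P - 1)) / P)
  phase <- as.vector(outer(w, w))
  Conj(kf) * phase
}

conv_fft_size <- function(H, W, k) stats::nextn(max(H, W) + k - 1, c(2, 3))

conv_fw <- function(x, H, W, B, Wmat, bias, k) {
  C <- ncol(x); Fn <- length(bias)
  pad <- (k - 1) / 2
  P <- conv_fft_size(H, W, k)
  xf <- conv_pad_fft(x, H, W, B, P, off = pad)        # input at offset pad
  kf <- kernel_fft(Wmat, k, C, Fn, P)
  kf_flip <- kernel_fft_flip(kf, k, P)
  dim(kf_flip) <- c(P * P, C * Fn)
  yf <- fft_conv_accum(xf, kf_flip, B, C, Fn)
  dim(yf) <- c(P, P, B * Fn)
  y <- Re(fft2_stack(yf, inverse = TRUE))
  y <- y[2 * pad + seq_len(H), 2 * pad + seq_len(W), , drop = FALSE]
  dim(y) <- c(H * W * B, Fn)
  y <- sweep(y, 2, bias, "+")
  list(out = y, xf = xf, kf = kf, P = P)
}

conv_bw <- function(dy, cache, Wmat, H, W, B, C_in, k) {
  Fn <- ncol(dy)
  pad <- (k - 1) / 2
  P <- cache$P
  dyf <- conv_pad_fft(dy, H, W, B, P, off = 0)        # gradient at offset 0
  kf <- cache$kf
  dim(kf) <- c(P * P, C_in * Fn)
  # dX: convolve upstream gradient with the (unflipped) kernel
  dxf <- fft_convT_accum(dyf, kf, B, C_in, Fn)
  dim(dxf) <- c(P, P, B * C_in)
  dx <- Re(fft2_stack(dxf, inverse = TRUE))
  dx <- dx[pad + seq_len(H), pad + seq_len(W), , drop = FALSE]
  dim(dx) <- c(H * W * B, C_in)
  # dW: cross-correlation of the cached input with the upstream gradient
  dwf <- fft_corr_accum(dyf, cache$xf, B, C_in, Fn)
  dim(dwf) <- c(P, P, C_in * Fn)
  dwfull <- Re(fft2_stack(dwf, inverse = TRUE))
  dW <- dwfull[seq_len(k), seq_len(k), , drop = FALSE]
  dim(dW) <- c(k * k, C_in, Fn)
  dW <- matrix(dW, k * k * C_in, Fn)
  list(dW = dW, db = colSums(dy), dx = dx)
}

# reference im2col implementation (exact same contract as conv_fw/conv_bw)
conv_fw_ref <- function(x, H, W, B, Wmat, bias, k) {
  xcol <- im2col_same(x, H, W, B, k)
  list(out = sweep(xcol %*% Wmat, 2, bias, "+"), xcol = xcol)
}

conv_bw_ref <- function(dy, cache_xcol, Wmat, H, W, B, C_in, k) {
  list(dW = crossprod(cache_xcol, dy),
       db = colSums(dy),
       dx = col2im_same(dy %*% t(Wmat), H, W, B, C_in, k))
}

#' Transposed convolution of an image stack with a fixed kernel
#'
#' The adjoint of "same"-padded stride-1 correlation: equivalently, each
#' input value stamps the (spatially flipped) kernel at its location, which
#' is what the decoder's upsampling convolutions compute. Exposed mainly so
#' the operation can be checked directly against hand-worked examples.
#'
#' @param x `(H*W*B) x C_in` feature-map matrix (see [batch4d_to_mat()]).
#' @param H,W,B Spatial height/width and batch size.
#' @param kernel Array `k x k x C_in x C_out`.
#' @return `(H*W*B) x C_out` matrix.
#' @export
conv_transpose2d <- function(x, H, W, B, kernel) {
  k <- dim(kernel)[1]
  stopifnot(dim(kernel)[2] == k, dim(kernel)[3] == ncol(x))
  flipped <- kernel[k:1, k:1, , , drop = FALSE]
  Wmat <- matrix(aperm(flipped, c(1, 2, 3, 4)),
                 k * k * dim(kernel)[3], dim(kernel)[4])
  conv_fw(x, H, W, B, Wmat, numeric(dim(kernel)[4]), k)$out
}

bn_fw <- function(x, gamma, beta, training, run_mean, run_var,
                  momentum = 0.1, eps = 1e-5) {
  if (training) {
    mu <- colMeans(x)
    v <- colMeans(sweep(x, 2, mu)^2)
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * v
  } else {
    mu <- run_mean; v <- run_var
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(x, 2, mu), 2, invstd, "*")
  out <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(out = out, xhat = xhat, invstd = invstd,
       run_mean = run_mean, run_var = run_var)
}

bn_bw <- function(dy, cache, gamma, training) {
  n <- nrow(dy)
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2, gamma, "*")
  dx <- if (training) {
    sweep(dxhat - matrix(colMeans(dxhat), n, ncol(dy), byrow = TRUE) -
            cache$xhat * matrix(colMeans(dxhat * cache$xhat), n, ncol(dy),
                                byrow = TRUE),
          2, cache$invstd, "*")
  } else {
    sweep(dxhat, 2, cache$invstd, "*")
  }
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# mean cross-entropy + gradient wrt logits; y is an index vector (1-based)
softmax_xent <- function(logits, y) {
  p <- softmax(logits)
  n <- nrow(p)
  loss <- -mean(log(pmax(p[cbind(seq_len(n), y)], 1e-12)))
  dz <- p
  dz[cbind(seq_len(n), y)] <- dz[cbind(seq_len(n), y)] - 1
  list(loss = loss, dlogits = dz / n, probs = p)
}

adam_init <- function(params) {
  flat <- rapply(params, function(p) p * 0, how = "replace")
  list(m = flat, v = flat, t = 0L)
}

adam_step <- function(state, params, grads, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^state$t)
    vh <- v / (1 - beta2^state$t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- list(p = p, m = m, v = v)
      keys <- if (is.null(names(p))) seq_along(p) else names(p)
      for (nm in keys) {
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out$p[[nm]] <- r$p; out$m[[nm]] <- r$m; out$v[[nm]] <- r$v
      }
      out
    } else upd(p, g, m, v)
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = state$t))
}
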