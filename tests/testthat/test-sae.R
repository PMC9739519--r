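test_that("config invariants: compression, odd kernels, valid penalty", {
  expect_error(sae_config(input_planes = 1, size = c(8, 8), kernels = 3,
                          filters = 4, bottleneck = 64), "compression")
  expect_error(sae_config(kernels = c(15, 8, 3)), "odd")
  expect_error(sae_config(lambda = -1), "lambda")
  expect_error(sae_config(size = c(60, 60)), "divisible")
  cfg <- sae_config()
  expect_equal(cfg$kernels, c(15L, 9L, 3L))
  expect_lt(cfg$bottleneck, prod(cfg$size) * cfg$input_planes)
})

test_that("encoder is deterministic, non-negative before projection, and
           propagates zeros through a zero-initialized net", {
  cfg <- sae_config(input_planes = 2, size = c(8, 8), kernels = c(3, 3),
                    filters = c(3, 4), bottleneck = 10, dropout = 0,
                    batchnorm = FALSE, seed = 3)
  net <- sae_init(cfg)
  withr::with_seed(1, x <- array(runif(8 * 8 * 2 * 3), c(8, 8, 2, 3)))
  z1 <- sae_encode(net, x)
  z2 <- sae_encode(net, x)
  expect_identical(z1, z2)
  expect_equal(dim(z1), c(3, 10))
  expect_error(sae_encode(net, array(0, c(8, 8, 5, 1))), "shape")
  # zero weights, zero input, no normalization -> exactly zero bottleneck
  net0 <- net
  net0$weights <- rapply(net0$weights, function(w) w * 0, how = "replace")
  z0 <- sae_encode(net0, array(0, c(8, 8, 2, 1)))
  expect_true(all(z0 == 0))
  # ReLU contract: pre-projection activations are non-negative
  bm <- emochart:::as_batch_mat(x)
  fw <- emochart:::enc_forward(net, bm$mat, 3, training = FALSE)
  expect_true(all(fw$flat >= 0))
})

test_that("decoder mirrors the encoder and unpooling routes to argmax", {
  cfg <- sae_config(input_planes = 2, size = c(8, 8), kernels = c(3, 3),
                    filters = c(3, 4), bottleneck = 10, dropout = 0, seed = 4)
  net <- sae_init(cfg)
  withr::with_seed(2, x <- array(runif(8 * 8 * 2 * 2), c(8, 8, 2, 2)))
  r <- sae_reconstruct(net, x)
  expect_equal(dim(r$xhat), dim(x))
  expect_error(sae_decode(net, r$z), "cache")
  # hand-worked 4x4 pooling example: values return to the argmax cells
  m <- matrix(c(1, 3, 2, 0, 5, 6, 0, 1, 0, 2, 4, 4, 8, 0, 1, 2), 16, 1)
  pl <- emochart:::maxpool2_fw(m, 4, 4, 1)
  expect_equal(as.vector(pl$values), c(6, 2, 8, 4))
  up <- emochart:::pool_scatter(pl$values, pl$idx, 16)
  expect_equal(sum(up != 0), 4)
  expect_equal(up[m == 6], 6)
  expect_equal(up[m == 8], 8)
  expect_equal(sum(up), sum(pl$values))
  # transpose convolution of an impulse stamps the kernel
  K <- array(0, c(3, 3, 1, 1)); K[, , 1, 1] <- matrix(1:9, 3)
  imp <- matrix(0, 25, 1); imp[13] <- 1
  out <- matrix(conv_transpose2d(imp, 5, 5, 1, K), 5, 5)
  expect_equal(out[2:4, 2:4], matrix(1:9, 3))
  expect_equal(sum(out), sum(1:9))
})

test_that("Fourier-domain convolution agrees with the patch-matrix route", {
  withr::with_seed(77, {
    for (shape in list(c(H = 16, W = 16, B = 3, C = 5, Fn = 4, k = 15),
                       c(H = 8, W = 8, B = 2, C = 3, Fn = 2, k = 9),
                       c(H = 7, W = 5, B = 2, C = 2, Fn = 3, k = 3))) {
      shape <- unname(shape)
      H <- shape[1]; W <- shape[2]; B <- shape[3]
      C <- shape[4]; Fn <- shape[5]; k <- shape[6]
      x <- matrix(rnorm(H * W * B * C), H * W * B, C)
      Wm <- matrix(rnorm(k * k * C * Fn), k * k * C, Fn)
      b <- rnorm(Fn)
      f1 <- emochart:::conv_fw(x, H, W, B, Wm, b, k)
      f2 <- emochart:::conv_fw_ref(x, H, W, B, Wm, b, k)
      expect_equal(f1$out, f2$out, tolerance = 1e-10)
      dy <- matrix(rnorm(H * W * B * Fn), H * W * B, Fn)
      b1 <- emochart:::conv_bw(dy, f1, Wm, H, W, B, C, k)
      b2 <- emochart:::conv_bw_ref(dy, f2$xcol, Wm, H, W, B, C, k)
      expect_equal(b1$dx, b2$dx, tolerance = 1e-10)
      expect_equal(b1$dW, b2$dW, tolerance = 1e-10)
      expect_equal(b1$db, b2$db, tolerance = 1e-10)
    }
  })
})

test_that("contractive penalty matches closed-form and finite differences", {
  # single linear layer b = W m: exact penalty is ||W||_F^2
  cfg <- sae_config(input_planes = 1, size = c(4, 4), kernels = 1,
                    filters = 1, bottleneck = 6, dropout = 0,
                    batchnorm = FALSE, seed = 5)
  net <- sae_init(cfg)
  # make the path linear: identity conv, pass-through pooling requires care,
  # so instead check the projection-only Jacobian against the chain rule on
  # a region where pooling/ReLU are locally linear
  withr::with_seed(3, x <- array(runif(16, 1, 2), c(4, 4, 1)))
  J <- encoder_jacobian(net, x)
  # finite differences
  xf <- as.vector(x)
  Jfd <- vapply(seq_along(xf), function(i) {
    e <- numeric(16); e[i] <- 1e-6
    (sae_encode(net, array(xf + e, c(4, 4, 1))) -
       sae_encode(net, array(xf - e, c(4, 4, 1)))) / 2e-6
  }, numeric(6))
  expect_equal(J, Jfd, tolerance = 1e-4, ignore_attr = TRUE)

  # true linear map: strip pooling by hand and compare against ||W||_F^2
  W <- matrix(rnorm(12), 3, 4)
  lin_pen <- sum(W^2)
  b <- function(m) as.vector(W %*% m)
  Jlin <- vapply(1:4, function(i) {
    e <- numeric(4); e[i] <- 1e-7
    (b(e) - b(-e)) / 2e-7
  }, numeric(3))
  expect_equal(sum(Jlin^2), lin_pen, tolerance = 1e-8)

  # small conv net: exact Jacobian penalty vs stochastic estimator
  cfg2 <- sae_config(input_planes = 2, size = c(4, 4), kernels = 3,
                     filters = 3, bottleneck = 5, dropout = 0,
                     batchnorm = FALSE, seed = 9)
  net2 <- sae_init(cfg2)
  withr::with_seed(4, xb <- array(runif(4 * 4 * 2 * 3), c(4, 4, 2, 3)))
  pen_exact <- mean(vapply(1:3, function(i)
    sum(encoder_jacobian(net2, xb[, , , i, drop = FALSE])^2), numeric(1)))
  pen_est <- contractive_penalty_estimate(net2, xb, n_probes = 3000,
                                          eps = 1e-4, seed = 6)
  expect_equal(pen_est, pen_exact, tolerance = 0.05)

  # lambda = 0 reduces exactly to the MSE
  r <- sae_reconstruct(net2, xb)
  l0 <- contractive_loss(net2, xb, r$xhat, lambda = 0)
  expect_identical(as.numeric(l0), mean((xb - r$xhat)^2))
  expect_error(contractive_loss(net2, xb, lambda = -0.1), "lambda")
})

test_that("training reduces loss, is seeded-reproducible, and memorizes a
           single image at zero penalty", {
  si <- stripe_images(n = 64, seed = 21)
  cfg <- tiny_sae_config(epochs = 10L)
  m1 <- sae_train(cfg, si$x)
  expect_true(all(is.finite(m1$loss_history)))
  expect_lt(tail(m1$loss_history, 1), 0.5 * m1$loss_history[1])
  m2 <- sae_train(cfg, si$x)
  expect_equal(m1$loss_history, m2$loss_history, tolerance = 1e-5)
  # single-image memorization: enough capacity, lambda = 0
  cfg1 <- sae_config(input_planes = 1, size = c(8, 8), kernels = 3,
                     filters = 8, bottleneck = 32, lambda = 0, dropout = 0,
                     batchnorm = FALSE, epochs = 400, batch_size = 1,
                     lr = 5e-3, seed = 2)
  withr::with_seed(5, x1 <- array(runif(64), c(8, 8, 1, 1)))
  mm <- sae_train(cfg1, x1)
  expect_lt(tail(mm$loss_history, 1), 1e-3)
})

test_that("the contractive weight trades reconstruction for contraction", {
  # over lambda in {0, 1e-4, 1e-2}: the Jacobian norm (measured by the
  # exact oracle) must fall as lambda rises, and reconstruction must be
  # worst where the penalty binds (1e-2). The 0 vs 1e-4 reconstruction
  # difference is below optimization noise at this scale, so those two are
  # compared as a tie rather than strictly ordered.
  withr::with_seed(31, x <- array(runif(8 * 8 * 48), c(8, 8, 1, 48)))
  fit_at <- function(lam) {
    cfg <- sae_config(input_planes = 1, size = c(8, 8), kernels = 3,
                      filters = 4, bottleneck = 12, lambda = lam,
                      dropout = 0, batchnorm = FALSE, epochs = 200,
                      batch_size = 48, lr = 5e-3, seed = 7)
    m <- sae_train(cfg, x)
    r <- sae_reconstruct(m, x)
    c(recon = mean((x - r$xhat)^2),
      pen = mean(vapply(seq(1, 48, by = 12), function(b)
        sum(encoder_jacobian(m, x[, , , b, drop = FALSE])^2), numeric(1))))
  }
  at0 <- fit_at(0); at4 <- fit_at(1e-4); at2 <- fit_at(1e-2)
  expect_gt(at0[["pen"]], at4[["pen"]])       # contraction increases with lambda
  expect_gt(at4[["pen"]], at2[["pen"]])
  noise <- 0.2 * at0[["recon"]]
  expect_lte(at0[["recon"]], at4[["recon"]] + noise)   # tie at sub-noise lambda
  expect_gt(at2[["recon"]], at0[["recon"]])   # binding penalty costs recon
  expect_gt(at2[["recon"]], at4[["recon"]])
})

test_that("feature extraction preserves order, batching and determinism", {
  si <- stripe_images(n = 40, seed = 41)
  cfg <- tiny_sae_config(epochs = 6L)
  m <- sae_train(cfg, si$x)
  f <- extract_features(m, si$x)
  expect_equal(dim(f), c(40, cfg$bottleneck))
  expect_true(all(is.finite(f)))
  # order equivariance
  perm <- rev(seq_len(40))
  fp <- extract_features(m, si$x[, , , perm, drop = FALSE])
  expect_equal(fp, f[perm, ], tolerance = 1e-12)
  # batched and single-item calls agree
  f1 <- extract_features(m, si$x[, , , 1:5, drop = FALSE], batch_size = 2L)
  expect_equal(f1, f[1:5, ], tolerance = 1e-6)
  # duplicate inputs give identical vectors
  dup <- si$x[, , , c(1, 1), drop = FALSE]
  fd <- extract_features(m, dup)
  expect_identical(fd[1, ], fd[2, ])
  # untrained params refuse extraction
  expect_error(extract_features(sae_init(cfg), si$x), "untrained")
})

test_that("unsupervised features carry class signal above chance", {
  si <- stripe_images(n = 96, seed = 51)
  m <- sae_train(tiny_sae_config(epochs = 8L), si$x)
  f <- extract_features(m, si$x)
  tr <- seq_len(64); te <- 65:96
  probe <- train_svm(f[tr, ], si$labels[tr])
  acc <- mean(predict(probe, f[te, ]) == si$labels[te])
  expect_gt(acc, 0.25)
})
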