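# Shared fixtures: tiny synthetic objects built in code at test time.

tiny_synth_spec <- function(seed = 1L, trial_s = 4, n_subjects = 1L,
                            trials_per_subject = 1L) {
  synth_preset("easy", n_subjects = n_subjects,
               trials_per_subject = trials_per_subject,
               trial_s = trial_s, seed = seed)
}

tiny_recording <- function(seed = 1L, quadrant = "HVHA", trial_s = 4) {
  generate_recording(tiny_synth_spec(seed, trial_s), quadrant, seed = seed)
}

# power of x in [lo, hi) Hz via the periodogram
bandpower <- function(x, fs, lo, hi) {
  n <- length(x)
  sp <- Mod(stats::fft(x))^2 / n
  fr <- (0:(n - 1)) * fs / n
  sum(sp[fr >= lo & fr < hi & fr <= fs / 2])
}

# small labeled scalogram-like image set with a class-dependent row stripe
stripe_images <- function(n = 120, size = 16L, planes = 3L, seed = 1L,
                          noise = 0.15) {
  withr::with_seed(seed, {
    x <- array(0, c(size, size, planes, n))
    labels <- character(n)
    h <- max(1L, size %/% 5)        # stripe height
    for (i in seq_len(n)) {
      cl <- (i - 1) %% 4
      r0 <- floor(cl * size / 4) + 1
      img <- matrix(0, size, size)
      img[r0:min(size, r0 + h), ] <- 1
      x[, , , i] <- array(rep(img, planes), c(size, size, planes)) *
        runif(1, 0.7, 1) + array(runif(size * size * planes, 0, noise),
                                 c(size, size, planes))
      labels[i] <- quadrant_levels()[cl + 1]
    }
    list(x = x, labels = labels)
  })
}

tiny_sae_config <- function(...) {
  defaults <- list(input_planes = 3L, size = c(16L, 16L), kernels = c(5L, 3L),
                   filters = c(6L, 8L), bottleneck = 24L, lambda = 1e-4,
                   dropout = 0.1, batchnorm = TRUE, epochs = 12L,
                   batch_size = 16L, lr = 2e-3, seed = 11L)
  do.call(sae_config, utils::modifyList(defaults, list(...)))
}

# separable 4-class feature clouds; class centers sit on +/- axes so any
# d >= 2 works
separable_features <- function(n_per_class = 30, d = 16, seed = 1L,
                               shift = 3) {
  withr::with_seed(seed, {
    f <- matrix(rnorm(4 * n_per_class * d, sd = 0.3), 4 * n_per_class, d)
    labels <- rep(quadrant_levels(), each = n_per_class)
    for (i in 1:4) {
      rows <- ((i - 1) * n_per_class + 1):(i * n_per_class)
      col <- ((i - 1) %% d) + 1
      sgn <- if ((i - 1) %/% d %% 2 == 0) 1 else -1
      f[rows, col] <- f[rows, col] + sgn * shift
    }
    list(features = f, labels = labels)
  })
}

# cache expensive shared fixtures across test files within one run
.fixture_env <- new.env(parent = emptyenv())

cached_fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, force(expr), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# a small but complete pipeline run shared by the pipeline and leakage tests
tiny_pipeline_run <- function() {
  cached_fixture("tiny_run", {
    cfg <- pipeline_config(
      scalogram_size = c(16L, 16L),
      sae = list(kernels = c(5L, 3L), filters = c(4L, 6L), bottleneck = 24L,
                 epochs = 3L, batch_size = 16L, lambda = 0, dropout = 0.1),
      classifiers = list(lstm_epochs = 10L), k = 4L, seed = 5L)
    run_pipeline(cfg, preset = "easy", n_subjects = 4L,
                 trials_per_subject = 2L)
  })
}
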