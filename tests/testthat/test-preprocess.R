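test_that("segmentation count follows floor((T - window)/hop) + 1", {
  rec <- tiny_recording(seed = 1, trial_s = 120)
  ss <- segment(rec, 30, 15)
  expect_length(ss, 7)
  expect_equal(ss$provenance$start_s, seq(0, 90, by = 15))
  expect_length(segment(tiny_recording(seed = 1, trial_s = 30), 30, 15), 1)
  expect_warning(ss0 <- segment(tiny_recording(seed = 1, trial_s = 29),
                                30, 15), "shorter")
  expect_length(ss0, 0)
  # every segment spans exactly window_s in every modality and carries
  # provenance and the trial label
  expect_true(all(vapply(ss$segments, function(s)
    all(vapply(s, ncol, integer(1)) == 30 * 128), logical(1))))
  expect_equal(ss$labels, rep(recording_label(rec), 7))
})

test_that("segmentation count formula holds over random durations", {
  rec0 <- tiny_recording(seed = 2, trial_s = 10)
  withr::with_seed(99, {
    for (i in 1:40) {
      T_s <- sample(5:240, 1)
      win <- sample(5:60, 1)
      hop <- sample(seq_len(win), 1)
      rec <- rec0
      n <- T_s * 128
      rec$signals <- lapply(rec0$signals, function(x)
        matrix(rnorm(nrow(x) * n), nrow(x)))
      expected <- if (T_s < win) 0 else floor((T_s - win) / hop) + 1
      got <- if (T_s < win) {
        expect_warning(s <- segment(rec, win, hop))
        length(s)
      } else length(segment(rec, win, hop))
      expect_equal(got, expected,
                   info = sprintf("T=%d win=%d hop=%d", T_s, win, hop))
    }
  })
})

test_that("bandpass keeps pass-band tones and rejects stop-band tones", {
  fs <- 128
  t <- (0:(60 * fs - 1)) / fs
  mid <- (length(t) %/% 4):(3 * length(t) %/% 4)
  eeg_spec <- filter_spec(0.5, 45)
  g10 <- max(abs(bandpass(sin(2 * pi * 10 * t), fs, eeg_spec)[mid]))
  expect_lt(abs(20 * log10(g10)), 1)             # within 1 dB
  g50 <- max(abs(bandpass(sin(2 * pi * 50 * t), fs, eeg_spec)[mid]))
  expect_lt(20 * log10(g50), -20)                # >= 20 dB down
  tg <- (0:(240 * fs - 1)) / fs
  midg <- (length(tg) %/% 4):(3 * length(tg) %/% 4)
  g01 <- max(abs(bandpass(sin(2 * pi * 0.1 * tg), fs,
                          filter_spec(0.04, 0.25))[midg]))
  expect_lt(abs(20 * log10(g01)), 1)
  expect_error(bandpass(sin(t), fs, filter_spec(1, 64)), "Nyquist")
  # matrix in, matrix of the same shape out
  m <- rbind(sin(2 * pi * 10 * t), cos(2 * pi * 10 * t))
  expect_equal(dim(bandpass(m, fs, eeg_spec)), dim(m))
})

test_that("pass-band filtering is nearly idempotent", {
  fs <- 128
  t <- (0:(60 * fs - 1)) / fs
  mid <- (length(t) %/% 4):(3 * length(t) %/% 4)
  sp <- filter_spec(0.5, 45)
  y1 <- bandpass(sin(2 * pi * 10 * t), fs, sp)
  y2 <- bandpass(y1, fs, sp)
  g1 <- max(abs(y1[mid])); g2 <- max(abs(y2[mid]))
  expect_lt(abs(20 * log10(g2 / g1)), 1)
})

test_that("ICA recovers known non-Gaussian sources up to sign/permutation", {
  t <- seq(0, 8, length.out = 2000)
  rs <- vapply(1:20, function(s) {
    withr::with_seed(1000 + s, {
      S <- rbind(sin(2 * pi * 3.7 * t),
                 2 * ((t * 2.3 + runif(1)) %% 1) - 1,
                 runif(length(t), -1, 1))
      repeat {                      # well-conditioned mixing
        A <- matrix(runif(9, -1, 1), 3, 3)
        if (kappa(A) < 15) break
      }
      m <- fit_ica(A %*% S, seed = s)
      min(apply(abs(cor(t(S), t(m$sources))), 1, max))
    })
  }, numeric(1))
  expect_gte(median(rs), 0.95)
})

test_that("ICA model satisfies its algebraic invariants", {
  withr::with_seed(5, {
    S <- rbind(sin(seq(0, 60, length.out = 1500)),
               runif(1500, -1, 1),
               2 * ((seq_len(1500) / 7.3) %% 1) - 1)
    A <- matrix(c(1, .4, .2, .5, 1.1, .3, .2, .6, .9), 3, 3)
    X <- A %*% S
  })
  m <- fit_ica(X, seed = 2)
  expect_equal(m$unmixing %*% m$mixing_estimate, diag(3), tolerance = 1e-8)
  expect_lt(max(abs(rowMeans(m$sources))), 1e-10)
  expect_equal(unname(apply(m$sources, 1, var)), rep(1, 3), tolerance = 1e-8)
  off <- abs(cor(t(m$sources)))[upper.tri(diag(3))]
  expect_lt(max(off), 1e-6)
  # reconstruction through the pseudo-inverse returns the centered input
  expect_equal(m$mixing_estimate %*% m$sources, X - rowMeans(X),
               tolerance = 1e-8)
  # deterministic under seed
  m2 <- fit_ica(X, seed = 2)
  expect_identical(m$unmixing, m2$unmixing)
  # applying to the fitted data reproduces the stored sources; the map is
  # linear, so doubling the input doubles the sources
  expect_equal(apply_ica(m, X), m$sources, tolerance = 1e-10)
  expect_equal(apply_ica(m, 2 * X), 2 * m$sources, tolerance = 1e-10)
  expect_error(apply_ica(m, X[1:2, ]), "channels")
})

test_that("ICA flags near-Gaussian inputs and rank deficiency", {
  withr::with_seed(8, g <- matrix(rnorm(3 * 1200), 3))
  expect_warning(
    try(fit_ica(g, seed = 1, max_iter = 25), silent = TRUE),
    "near-zero excess kurtosis")
  x <- matrix(rnorm(2 * 600), 2)
  expect_error(fit_ica(rbind(x, x[1, ] + x[2, ]), seed = 1),
               "rank-deficient")
  expect_error(fit_ica(matrix(rnorm(42), 14), seed = 1), "samples")
})

test_that("whole-trial preprocessing yields ICA-source segments", {
  cfg <- pipeline_config(seed = 3)
  rec <- tiny_recording(seed = 51, trial_s = 60)
  ss <- preprocess_recording(rec, cfg)
  expect_length(ss, 3)    # floor((60 - 30)/15) + 1
  seg <- ss$segments[[1]]
  expect_equal(nrow(seg$EEG), 14)  # all sources forwarded, none discarded
  expect_equal(nrow(seg$ECG), 2)   # ECG/GSR bypass ICA
  # powerline tone is strongly attenuated in the filtered output
  before <- bandpower(rec$signals$EEG[1, ], 128, 49.9, 50.1)
  segs_cat <- do.call(cbind, lapply(ss$segments, `[[`, "ECG"))
  filt <- bandpass(rec$signals$EEG[1, ], 128, filter_spec(0.5, 45))
  after <- bandpower(filt, 128, 49.9, 50.1)
  expect_gt(10 * log10(before / after), 20)
})
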