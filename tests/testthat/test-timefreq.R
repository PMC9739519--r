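test_that("Haar one-level transform matches the hand-worked example", {
  d <- dwt_decompose(c(1, 2, 3, 4), wavelet_spec("haar", 1))
  expect_equal(d$approx, c(3, 7) / sqrt(2), tolerance = 1e-12)
  expect_equal(d$details[[1]], c(-1, -1) / sqrt(2), tolerance = 1e-12)
  expect_equal(round(d$approx, 4), c(2.1213, 4.9497))
  expect_equal(round(d$details[[1]], 4), c(-0.7071, -0.7071))
  o <- dwt_oracle(c(1, 2, 3, 4), wavelet_spec("haar", 1))
  expect_equal(o$approx, d$approx)
  expect_equal(o$details, d$details)
})

test_that("quadrature-mirror relation links the filter pair", {
  for (nm in c("haar", "db2", "db4")) {
    w <- wavelet_spec(nm)
    m <- seq_along(w$lo) - 1
    expect_equal(w$hi, (-1)^m * rev(w$lo))
    expect_equal(sum(w$lo^2), 1, tolerance = 1e-12)   # unit L2 norm
    expect_lt(abs(sum(w$hi)), 1e-10)                  # vanishing moment
  }
  expect_error(wavelet_spec("sym9"), "unknown wavelet")
})

test_that("orthonormal wavelets reconstruct perfectly", {
  withr::with_seed(7, {
    for (i in 1:100) {
      nm <- sample(c("haar", "db2", "db3", "db4"), 1)
      L <- sample(1:4, 1)
      x <- rnorm(512)
      spec <- wavelet_spec(nm, L)
      expect_lt(max(abs(inverse_dwt(dwt_decompose(x, spec)) - x)), 1e-8)
    }
  })
})

test_that("periodic-boundary transform conserves energy", {
  withr::with_seed(8, {
    for (i in 1:20) {
      x <- rnorm(256)
      d <- dwt_decompose(x, wavelet_spec("db4", 4))
      e <- sum(d$approx^2) + sum(unlist(d$details)^2)
      expect_equal(e, sum(x^2), tolerance = 1e-6)
    }
  })
})

test_that("pyramid transform equals the convolution-decimation oracle", {
  withr::with_seed(9, {
    for (i in 1:50) {
      n <- sample(c(64, 128, 256), 1)
      nm <- sample(c("haar", "db2", "db4"), 1)
      L <- sample(1:3, 1)
      x <- rnorm(n)
      spec <- wavelet_spec(nm, L)
      a <- dwt_decompose(x, spec)
      b <- dwt_oracle(x, spec)
      expect_lt(max(abs(a$approx - b$approx)), 1e-10)
      expect_lt(max(abs(unlist(a$details) - unlist(b$details))), 1e-10)
    }
  })
})

test_that("impulse response at level 1 is the time-reversed filter", {
  # with approx[k] = sum_m lo[m] x[2k + m], a unit impulse at position p
  # produces lo[p - 2k] over k: reading the level-1 sequence recovers the
  # filter taps (time-reversed across k)
  spec <- wavelet_spec("db2", 1)
  p <- 8                          # impulse position, 0-based
  x <- numeric(32); x[p + 1] <- 1
  d <- dwt_decompose(x, spec)
  expected <- function(taps) vapply(0:15, function(k) {
    m <- (p - 2 * k) %% 32
    if (m < length(taps)) taps[m + 1] else 0
  }, numeric(1))
  expect_equal(d$approx, expected(spec$lo), tolerance = 1e-12)
  expect_equal(d$details[[1]], expected(spec$hi), tolerance = 1e-12)
})

test_that("degenerate and invalid inputs are handled", {
  # constant signal: all details vanish (one vanishing moment)
  d <- dwt_decompose(rep(3, 64), wavelet_spec("db4", 3))
  expect_lt(max(abs(unlist(d$details))), 1e-12)
  expect_equal(inverse_dwt(d), rep(3, 64), tolerance = 1e-10)
  # zeroing details of a constant signal leaves it unchanged
  d$details <- lapply(d$details, function(v) v * 0)
  expect_equal(inverse_dwt(d), rep(3, 64), tolerance = 1e-10)
  expect_error(dwt_decompose(rnorm(24), wavelet_spec("db4", 4)), "at most")
  d2 <- dwt_decompose(rnorm(64), wavelet_spec("db2", 2))
  d2$details[[1]] <- d2$details[[1]][-1]
  expect_error(inverse_dwt(d2), "length")
})

test_that("removing the approximation removes the low-band energy", {
  # signal built as a low-band part plus a high-band part with equal energy:
  # zeroing the approximation halves total energy (Parseval)
  fs <- 128
  t <- (0:511) / fs
  lo_part <- sin(2 * pi * 1 * t)
  hi_part <- sin(2 * pi * 40 * t)
  lo_part <- lo_part / sqrt(sum(lo_part^2))
  hi_part <- hi_part / sqrt(sum(hi_part^2))
  x <- lo_part + hi_part
  d <- dwt_decompose(x, wavelet_spec("db4", 5))
  d$approx <- d$approx * 0
  # levels 4-5 also carry the 1 Hz band at fs = 128; drop them too
  d$details[[5]] <- d$details[[5]] * 0
  d$details[[4]] <- d$details[[4]] * 0
  r <- inverse_dwt(d)
  expect_equal(sum(r^2) / sum(x^2), 0.5, tolerance = 0.05)
})

test_that("scalogram assembly is normalized, dyadic and degenerate-safe", {
  x <- rnorm(512)
  d <- dwt_decompose(x, wavelet_spec("db4", 4))
  sg <- build_scalogram(d, c(16, 16), channel = "EEG1")
  expect_equal(dim(sg$image), c(16, 16))
  expect_true(all(sg$image >= 0 & sg$image <= 1))
  expect_equal(range(sg$image), c(0, 1))
  expect_equal(sg$level_map[1], "approx")
  expect_equal(sg$level_map[16], "d1")
  # finest band occupies half the conceptual rows
  expect_equal(sum(sg$level_map == "d1"), 8)
  # all-zero input -> all-zero image, no division by zero
  z <- build_scalogram(dwt_decompose(numeric(512), wavelet_spec("db4", 4)),
                       c(16, 16))
  expect_true(all(z$image == 0))
})

test_that("tones land in their analytic sub-band row block", {
  fs <- 128
  t <- (0:(30 * fs - 1)) / fs
  spec <- wavelet_spec("db4", 5)
  locate <- function(f) {
    sg <- build_scalogram(dwt_decompose(sin(2 * pi * f * t), spec), c(32, 32))
    sg$level_map[which.max(apply(sg$image, 1, max))]
  }
  expect_equal(locate(30), "d2")   # 16-32 Hz band
  expect_true(locate(2) %in% c("approx", "d5"))  # 2-4 Hz band edge
  # band centers across all levels: >= 95% localized correctly
  rng <- dwt_band_ranges(fs, 5)
  centers <- sqrt(rng$low_hz * rng$high_hz)[-1]   # detail bands
  hits <- mapply(function(f, b) locate(f) == b, centers, rng$band[-1])
  expect_gte(mean(hits), 0.95)
})

test_that("per-segment scalogram stacks have one plane per channel", {
  rec <- tiny_recording(seed = 61, trial_s = 30)
  cfg <- pipeline_config(scalogram_size = c(16L, 16L), seed = 2)
  ss <- segment(rec, 30, 15)
  st <- scalogram_stack(ss$segments[[1]], cfg)
  expect_equal(dim(st), c(16, 16, 17))
  batch <- segment_scalograms(ss, cfg)
  expect_equal(dim(batch$x), c(16, 16, 17, 1))
  expect_true(all(is.finite(batch$x)))
})
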