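#' Bandpass filter specification
#'
#' @param low,high Pass-band edges in Hz, `0 < low < high`.
#' @param order Butterworth prototype order (default 4).
#' @param zero_phase Apply forward-backward (no group delay); default `TRUE`.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(low, high, order = 4L, zero_phase = TRUE) {
  stopifnot(low > 0, high > low, order >= 1)
  structure(list(low = low, high = high, order = as.integer(order),
                 zero_phase = isTRUE(zero_phase)), class = "filter_spec")
}

# Butterworth bandpass designed in zero-pole-gain form and returned as a
# cascade of biquad sections. Designing directly in second-order sections
# keeps the filter numerically stable at very low normalized frequencies
# (e.g. the 0.04-0.25 Hz skin-conductance band at 128 Hz), where the
# expanded transfer-function polynomial is unusable.
butter_bandpass_sos <- function(order, low, high, fs) {
  n <- order
  k <- seq_len(n)
  p_proto <- exp(1i * pi * (2 * k + n - 1) / (2 * n))  # analog lowpass poles
  w1 <- 2 * fs * tan(pi * low / fs)                    # prewarped edges
  w2 <- 2 * fs * tan(pi * high / fs)
  w0 <- sqrt(w1 * w2); bw <- w2 - w1
  pb <- complex(0)
  for (pp in p_proto) {                                # lowpass -> bandpass
    b2 <- pp * bw / 2
    disc <- sqrt(b2^2 - w0^2)
    pb <- c(pb, b2 + disc, b2 - disc)
  }
  zd <- (2 * fs + pb) / (2 * fs - pb)                  # bilinear transform

  tol <- 1e-8 * max(Mod(zd))
  cplx <- zd[Im(zd) > tol]
  real <- sort(Re(zd[abs(Im(zd)) <= tol]))
  sos <- list()
  for (p in cplx)
    sos[[length(sos) + 1]] <- c(1, -2 * Re(p), Mod(p)^2)
  if (length(real) %% 2 != 0)
    stop("butter_bandpass_sos: unpaired real pole (degenerate band)")
  for (i in seq_len(length(real) / 2))
    sos[[length(sos) + 1]] <- c(1, -(real[2 * i - 1] + real[2 * i]),
                                real[2 * i - 1] * real[2 * i])
  # each section gets one zero at z = 1 and one at z = -1: numerator z^2 - 1;
  # unit gain is imposed at the true response peak, the digital image of the
  # prewarped analog center frequency
  wc <- 2 * atan(w0 / (2 * fs))
  zc <- exp(1i * wc)
  h <- prod(vapply(sos, function(a)
    (zc^2 - 1) / (zc^2 + a[2] * zc + a[3]), complex(1)))
  g <- 1 / Mod(h)
  lapply(seq_along(sos), function(i) {
    gi <- if (i == 1) g else 1
    list(b = gi * c(1, 0, -1), a = sos[[i]])
  })
}

sos_response <- function(sos, f, fs) {
  z <- exp(1i * 2 * pi * f / fs)
  vapply(z, function(zz) prod(vapply(sos, function(s)
    sum(s$b * zz^(2:0)) / sum(s$a * zz^(2:0)), complex(1))), complex(1))
}

#' Bandpass-filter a multichannel signal
#'
#' Butterworth bandpass (biquad cascade), applied forward-backward when
#' `spec$zero_phase` so waveform morphology is not delayed or skewed. Output
#' has the shape of the input.
#'
#' @param x Channel-by-time numeric matrix (a plain vector is treated as one
#'   channel).
#' @param rate Sampling rate in Hz.
#' @param spec A [filter_spec()].
#' @return Filtered matrix of the same shape.
#' @export
bandpass <- function(x, rate, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  if (spec$high >= rate / 2)
    stop("bandpass: high cut-off ", spec$high,
         " Hz is not below the Nyquist frequency ", rate / 2, " Hz")
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, 1)
  sos <- butter_bandpass_sos(spec$order, spec$low, spec$high, rate)
  # odd-reflection padding sized to the slowest pole's decay, so the
  # zero-phase startup transients die out inside the padding
  maxr <- max(vapply(sos, function(s) max(Mod(polyroot(rev(s$a)))),
                     numeric(1)))
  npad <- min(ncol(x) - 1, max(64, ceiling(-9 / log(maxr))))
  out <- x
  for (i in seq_len(nrow(x))) {
    v <- out[i, ]
    n <- length(v)
    vp <- c(2 * v[1] - v[(npad + 1):2], v, 2 * v[n] - v[(n - 1):(n - npad)])
    for (s in sos) {
      flt <- signal::Arma(b = s$b, a = s$a)
      vp <- if (spec$zero_phase) signal::filtfilt(flt, vp)
            else as.numeric(signal::filter(flt, vp))
    }
    out[i, ] <- vp[(npad + 1):(npad + n)]
  }
  if (vec) drop(out) else out
}

#' Cut a recording into overlapping fixed-length windows
#'
#' Produces `floor((T - window_s) / hop_s) + 1` windows for a trial of
#' duration `T` seconds; trailing partial windows are dropped, and a trial
#' shorter than one window yields an empty set with a warning.
#'
#' @param rec A [recording()].
#' @param window_s Window length in seconds (default 30).
#' @param hop_s Hop between window starts in seconds (default 15, i.e. 50%
#'   overlap).
#' @return An object of class `segment_set`: list with `segments` (each a
#'   named list of channel-by-time matrices), `labels`, and a `provenance`
#'   data frame (subject, trial, window start in seconds).
#' @export
segment <- function(rec, window_s = 30, hop_s = 15) {
  stopifnot(hop_s > 0, window_s > 0, hop_s <= window_s)
  T_s <- recording_duration(rec)
  n_win <- if (T_s < window_s) 0L
           else as.integer(floor((T_s - window_s) / hop_s + 1e-9)) + 1L
  if (n_win == 0L) {
    warning("segment: trial ", rec$trial_id, " (", T_s,
            " s) is shorter than one ", window_s, " s window")
    return(empty_segment_set())
  }
  label <- recording_label(rec)
  segments <- vector("list", n_win)
  starts <- (seq_len(n_win) - 1) * hop_s
  for (w in seq_len(n_win)) {
    seg <- list()
    for (m in names(rec$signals)) {
      r <- rec$sampling_rates[[m]]
      i0 <- round(starts[w] * r)
      seg[[m]] <- rec$signals[[m]][, (i0 + 1):(i0 + round(window_s * r)),
                                   drop = FALSE]
    }
    segments[[w]] <- seg
  }
  structure(list(
    segments = segments,
    labels = rep(label, n_win),
    provenance = data.frame(subject_id = rec$subject_id,
                            trial_id = rec$trial_id,
                            start_s = starts, stringsAsFactors = FALSE)),
    class = "segment_set")
}

empty_segment_set <- function() {
  structure(list(segments = list(), labels = character(0),
                 provenance = data.frame(subject_id = character(0),
                                         trial_id = character(0),
                                         start_s = numeric(0))),
            class = "segment_set")
}

#' Concatenate segment sets
#'
#' @param ... `segment_set` objects (or a single list of them).
#' @return One combined `segment_set`.
#' @export
bind_segment_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && !inherits(sets[[1]], "segment_set"))
    sets <- sets[[1]]
  structure(list(
    segments = do.call(c, lapply(sets, `[[`, "segments")),
    labels = do.call(c, lapply(sets, `[[`, "labels")),
    provenance = do.call(rbind, lapply(sets, `[[`, "provenance"))),
    class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat("<segment_set>", length(x$segments), "segments\n")
  if (length(x$segments)) {
    tb <- table(x$labels, useNA = "ifany")
    cat("  labels:", paste(names(tb), tb, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
length.segment_set <- function(x) length(x$segments)

# --- ICA ------------------------------------------------------------------

sym_decorrelate <- function(W) {
  e <- eigen(W %*% t(W), symmetric = TRUE)
  e$vectors %*% diag(1 / sqrt(pmax(e$values, .Machine$double.eps)),
                     nrow(W)) %*% t(e$vectors) %*% W
}

pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d)
  s$v[, keep, drop = FALSE] %*% diag(1 / s$d[keep], sum(keep)) %*%
    t(s$u[, keep, drop = FALSE])
}

#' Fit an independent component analysis model to EEG channels
#'
#' Linear noiseless unmixing of the observed channels into statistically
#' independent sources, estimated with the fixed-point scheme: PCA whitening
#' followed by a symmetric-decorrelation fixed-point iteration with a
#' `tanh` contrast. With a fixed seed the fit is deterministic. All sources
#' are retained by default (no component rejection); an optional kurtosis
#' threshold can drop low-kurtosis components.
#'
#' @param eeg Channel-by-time numeric matrix.
#' @param seed Integer seed for the random orthonormal initialization.
#' @param n_sources Number of sources to extract (default: all channels).
#' @param max_iter,tol Fixed-point iteration controls.
#' @param reject_kurtosis `NULL` (keep everything, the default) or a
#'   threshold: components with absolute excess kurtosis below it are
#'   dropped from the returned sources.
#' @return An object of class `ica_model` with the whitening matrix, the
#'   unmixing matrix (sources = unmixing %*% centered data), the
#'   pseudo-inverse mixing estimate and the source matrix.
#' @export
fit_ica <- function(eeg, seed = 1L, n_sources = nrow(eeg),
                    max_iter = 500L, tol = 1e-5, reject_kurtosis = NULL) {
  stopifnot(is.matrix(eeg))
  d <- nrow(eeg); T_n <- ncol(eeg); m <- as.integer(n_sources)
  if (!all(is.finite(eeg))) stop("fit_ica: non-finite values in input")
  if (T_n < 10 * d)
    stop("fit_ica: need at least 10 x ", d, " = ", 10 * d,
         " samples, got ", T_n)
  ctr <- rowMeans(eeg)
  xc <- eeg - ctr
  cv <- tcrossprod(xc) / (T_n - 1)
  e <- eigen(cv, symmetric = TRUE)
  if (any(e$values < 1e-12 * max(e$values)))
    stop("fit_ica: rank-deficient input; dimension(s) ",
         paste(which(e$values < 1e-12 * max(e$values)), collapse = ", "),
         " of the whitening basis carry (numerically) zero variance")
  K <- diag(1 / sqrt(e$values[1:m]), m) %*% t(e$vectors[, 1:m, drop = FALSE])
  Z <- K %*% xc

  zkurt <- rowMeans(Z^4) / rowMeans(Z^2)^2 - 3
  # threshold sits 3 sampling-noise SDs (var of excess kurtosis ~ 24/T for
  # Gaussian data) above zero, so truly Gaussian inputs trigger it
  if (all(abs(zkurt) < max(0.1, 3 * sqrt(24 / T_n))))
    warning("fit_ica: all whitened components have near-zero excess ",
            "kurtosis (near-Gaussian data); independent sources are weakly ",
            "identifiable and the iteration may not converge")

  W <- withr::with_seed(seed, matrix(rnorm(m * m), m, m))
  W <- sym_decorrelate(W)
  delta <- Inf
  for (it in seq_len(max_iter)) {
    G <- tanh(W %*% Z)
    W1 <- G %*% t(Z) / T_n - diag(rowMeans(1 - G^2), m) %*% W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) break
  }
  if (delta >= tol)
    stop("fit_ica: no convergence after ", max_iter,
         " iterations (last step change ", signif(delta, 3),
         ", tolerance ", tol, ")")

  Y <- W %*% K
  S <- W %*% Z
  keep <- seq_len(m)
  if (!is.null(reject_kurtosis)) {
    sk <- abs(rowMeans(S^4) / rowMeans(S^2)^2 - 3)
    keep <- which(sk >= reject_kurtosis)
    Y <- Y[keep, , drop = FALSE]; S <- S[keep, , drop = FALSE]
  }
  structure(list(n_sources = length(keep), n_channels = d,
                 center = ctr, whitening = K, unmixing = Y,
                 mixing_estimate = pinv(Y), sources = S,
                 iterations = it, seed = seed),
            class = "ica_model")
}

#' @export
print.ica_model <- function(x, ...) {
  cat("<ica_model>", x$n_sources, "sources from", x$n_channels,
      "channels; converged in", x$iterations, "iterations\n")
  invisible(x)
}

#' Unmix a recording's EEG with a fitted ICA model
#'
#' Applies the learned unmixing to (row-centered) data: the estimated source
#' signals, not back-projected channels, are what the downstream wavelet
#' stage consumes. Centering is recomputed per call, so the map is linear in
#' the input.
#'
#' @param model An `ica_model` from [fit_ica()].
#' @param eeg Channel-by-time matrix with the channel count the model was
#'   fitted on.
#' @return Sources-by-time matrix.
#' @export
apply_ica <- function(model, eeg) {
  stopifnot(inherits(model, "ica_model"))
  if (!is.matrix(eeg) || nrow(eeg) != model$n_channels)
    stop("apply_ica: input has ", nrow(eeg), " channels, model was fitted on ",
         model$n_channels)
  model$unmixing %*% (eeg - rowMeans(eeg))
}

#' Filter, unmix and segment one recording
#'
#' The standard preprocessing order: bandpass filter each modality over the
#' whole trial (avoiding window-edge transients, essential for the 0.04 Hz
#' GSR cut-off), run ICA on the filtered EEG (per trial) and replace the EEG
#' channels by the estimated sources, then cut into overlapping windows.
#'
#' @param rec A [recording()].
#' @param config A [pipeline_config()].
#' @param bandpass_on Apply the per-modality bandpass filters (default
#'   `TRUE`; the ablation harness disables it).
#' @param ica_on Apply ICA to EEG (defaults to `config$ica`).
#' @return A `segment_set`.
#' @export
preprocess_recording <- function(rec, config = pipeline_config(),
                                 bandpass_on = TRUE, ica_on = config$ica) {
  sig <- rec$signals
  if (bandpass_on) {
    for (m in names(sig)) {
      ms <- config$modalities[[m]]
      if (is.null(ms)) next
      sig[[m]] <- bandpass(sig[[m]], rec$sampling_rates[[m]],
                           filter_spec(ms$band[1], ms$band[2]))
    }
  }
  if (ica_on && !is.null(sig$EEG) && nrow(sig$EEG) > 1) {
    mod <- fit_ica(sig$EEG, seed = config$seed, max_iter = 1000L)
    sig$EEG <- apply_ica(mod, sig$EEG)
  }
  rec$signals <- sig
  segment(rec, config$window_s, config$hop_s)
}
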