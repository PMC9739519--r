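# Scalogram assembly: a 2-D time-scale image built from DWT sub-band
# coefficients. Layout (top to bottom): the level-L approximation occupies
# one conceptual row, then the detail bands from coarsest (level L) to
# finest (level 1), the level-j band replicated 2^(L-j)-fold, giving 2^L
# conceptual rows. Cells hold log(1 + |coefficient|), each band is spread
# along the time axis, the image is min-max normalized to [0, 1]
# (an all-zero band structure maps to an all-zero image), and finally
# resampled to the requested (H, W).

resample_vec <- function(v, w) {
  n <- length(v)
  if (n == w) return(v)
  if (n >= w) {
    breaks <- floor(seq(0, n, length.out = w + 1))
    vapply(seq_len(w), function(t)
      mean(v[(breaks[t] + 1):breaks[t + 1]]), numeric(1))
  } else {
    v[ceiling(seq_len(w) * n / w)]
  }
}

#' Build a scalogram image from wavelet coefficients
#'
#' @param coeffs A `dwt_coeffs` object from [dwt_decompose()].
#' @param size Length-2 integer `(H, W)` of the output image (default 64x64).
#' @param channel Optional channel identifier carried along.
#' @return An object of class `scalogram`: `image` (HxW matrix in `[0, 1]`),
#'   `channel`, and `level_map` (per output row, which sub-band it came
#'   from: `"approx"`, `"d<L>"` .. `"d1"`).
#' @export
build_scalogram <- function(coeffs, size = c(64, 64), channel = NA) {
  stopifnot(inherits(coeffs, "dwt_coeffs"), length(size) == 2)
  H <- as.integer(size[1]); W <- as.integer(size[2])
  L <- length(coeffs$details)
  bands <- c(list(coeffs$approx), rev(coeffs$details))   # approx, dL, ..., d1
  band_names <- c("approx", paste0("d", L:1))
  reps <- c(1L, 2^(L - (L:1)))                            # rows per band
  grid <- matrix(0, 2^L, W)
  row_band <- character(2^L)
  r <- 0L
  for (i in seq_along(bands)) {
    rowvals <- resample_vec(log1p(abs(bands[[i]])), W)
    for (k in seq_len(reps[i])) {
      r <- r + 1L
      grid[r, ] <- rowvals
      row_band[r] <- band_names[i]
    }
  }
  rng <- range(grid)
  grid <- if (diff(rng) > 0) (grid - rng[1]) / diff(rng) else grid * 0
  # resample rows to H (block mean when shrinking, replication when growing)
  img <- apply(grid, 2, resample_vec, w = H)
  if (H == 1) img <- matrix(img, 1)
  lev <- row_band[pmin(2^L, ceiling(seq_len(H) * 2^L / H))]
  structure(list(image = img, channel = channel, level_map = lev),
            class = "scalogram")
}

#' @export
print.scalogram <- function(x, ...) {
  cat("<scalogram>", nrow(x$image), "x", ncol(x$image),
      if (!is.na(x$channel)) paste("channel", x$channel) else "", "\n")
  invisible(x)
}

#' Analytic sub-band frequency ranges of a dyadic decomposition
#'
#' Detail level j of a signal sampled at `rate` covers
#' `rate / 2^(j+1)` .. `rate / 2^j` Hz; the approximation covers everything
#' below `rate / 2^(L+1)`.
#'
#' @param rate Sampling rate in Hz.
#' @param levels Decomposition depth L.
#' @return Data frame with `band`, `low_hz`, `high_hz`.
#' @export
dwt_band_ranges <- function(rate, levels) {
  data.frame(
    band = c("approx", paste0("d", levels:1)),
    low_hz = c(0, rate / 2^((levels:1) + 1)),
    high_hz = c(rate / 2^(levels + 1), rate / 2^(levels:1)))
}

#' Scalogram stack of one multimodal segment
#'
#' Computes one scalogram per channel of every modality (EEG sources first,
#' then ECG, then GSR, in the segment's modality order) and stacks them as
#' the planes of a single image.
#'
#' @param seg Named list of channel-by-time matrices (one entry of a
#'   `segment_set`).
#' @param config A [pipeline_config()] (wavelet, levels, scalogram size).
#' @return Numeric array `H x W x C`.
#' @export
scalogram_stack <- function(seg, config = pipeline_config()) {
  spec <- wavelet_spec(config$wavelet, config$levels)
  sz <- config$scalogram_size
  mats <- lapply(names(seg), function(m) {
    x <- seg[[m]]
    lapply(seq_len(nrow(x)), function(i)
      build_scalogram(dwt_decompose(x[i, ], spec), sz,
                      channel = paste0(m, i))$image)
  })
  imgs <- do.call(c, mats)
  array(unlist(imgs), dim = c(sz[1], sz[2], length(imgs)))
}

#' Scalogram batch for a whole segment set
#'
#' @param segset A `segment_set`.
#' @param config A [pipeline_config()].
#' @return List with `x` (array `H x W x C x n`), `labels`, `provenance`.
#' @export
segment_scalograms <- function(segset, config = pipeline_config()) {
  stopifnot(inherits(segset, "segment_set"))
  n <- length(segset$segments)
  if (n == 0) stop("segment_scalograms: empty segment set")
  stacks <- lapply(segset$segments, scalogram_stack, config = config)
  d <- dim(stacks[[1]])
  x <- array(unlist(stacks), dim = c(d, n))
  list(x = x, labels = segset$labels, provenance = segset$provenance)
}
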