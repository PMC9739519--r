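#' Describe one signal modality
#'
#' A modality spec names a signal type (EEG, ECG or GSR), its channel count,
#' sampling rate and analysis pass-band. The defaults mirror a 14-channel EEG
#' headset plus 2-lead ECG and single-channel GSR, all sampled at 128 Hz, with
#' the conventional pass-bands: 0.5-45 Hz for EEG and ECG (powerline and
#' baseline rejection) and 0.04-0.25 Hz for GSR (the skin-conductance
#' response band).
#'
#' @param name One of `"EEG"`, `"ECG"`, `"GSR"`.
#' @param n_channels Positive integer channel count.
#' @param sampling_rate Sampling rate in Hz.
#' @param band Length-2 numeric, filter pass-band `(low, high)` in Hz.
#' @return An object of class `modality_spec`.
#' @export
modality_spec <- function(name = c("EEG", "ECG", "GSR"),
                          n_channels = NULL,
                          sampling_rate = 128,
                          band = NULL) {
  name <- match.arg(name)
  if (is.null(n_channels))
    n_channels <- switch(name, EEG = 14L, ECG = 2L, GSR = 1L)
  if (is.null(band))
    band <- switch(name, EEG = c(0.5, 45), ECG = c(0.5, 45),
                   GSR = c(0.04, 0.25))
  n_channels <- as.integer(n_channels)
  stopifnot(length(band) == 2, n_channels >= 1L, sampling_rate > 0)
  if (!(band[1] > 0 && band[1] < band[2]))
    stop("modality_spec: need 0 < low < high in the pass-band")
  if (band[2] >= sampling_rate / 2)
    stop("modality_spec: high cut-off ", band[2],
         " Hz must be below the Nyquist frequency ", sampling_rate / 2, " Hz")
  structure(list(name = name, n_channels = n_channels,
                 sampling_rate = sampling_rate, band = band),
            class = "modality_spec")
}

#' Default modality layout: 14-channel EEG + 2-channel ECG + 1-channel GSR
#'
#' @param sampling_rate Common sampling rate in Hz (default 128).
#' @return Named list of [modality_spec()] objects.
#' @export
default_modalities <- function(sampling_rate = 128) {
  list(EEG = modality_spec("EEG", sampling_rate = sampling_rate),
       ECG = modality_spec("ECG", sampling_rate = sampling_rate),
       GSR = modality_spec("GSR", sampling_rate = sampling_rate))
}

#' Construct a multimodal recording
#'
#' A recording holds one trial of multichannel signals, one channels-by-time
#' matrix per modality, together with its sampling rates and the self-reported
#' valence/arousal ratings on a bounded scale.
#'
#' @param subject_id,trial_id Identifier strings.
#' @param signals Named list of channel-by-time numeric matrices (names are
#'   modality names).
#' @param sampling_rates Named numeric vector of sampling rates in Hz, one per
#'   modality in `signals`.
#' @param valence,arousal Self-report ratings; `NA` marks an unlabeled trial.
#' @param scale_bounds Length-2 numeric `(min, max)` of the rating scale.
#' @param modalities Named list of [modality_spec()] used to validate channel
#'   counts; `NULL` skips the channel-count check.
#' @return An object of class `recording`.
#' @export
recording <- function(subject_id, trial_id, signals, sampling_rates,
                      valence = NA_real_, arousal = NA_real_,
                      scale_bounds = c(1, 9), modalities = NULL) {
  stopifnot(is.list(signals), length(signals) >= 1,
            !is.null(names(signals)), length(scale_bounds) == 2,
            scale_bounds[1] < scale_bounds[2])
  for (m in names(signals)) {
    x <- signals[[m]]
    if (!is.matrix(x) || !is.numeric(x))
      stop("recording: signals[['", m, "']] must be a numeric matrix")
    if (is.null(sampling_rates[[m]]))
      stop("recording: no sampling rate for modality '", m, "'")
    if (!is.null(modalities) && !is.null(modalities[[m]]) &&
        nrow(x) != modalities[[m]]$n_channels)
      stop("recording: modality '", m, "' has ", nrow(x),
           " channels, expected ", modalities[[m]]$n_channels)
  }
  for (r in c(valence, arousal))
    if (!is.na(r) && (r < scale_bounds[1] || r > scale_bounds[2]))
      stop("recording: rating ", r, " outside scale bounds [",
           scale_bounds[1], ", ", scale_bounds[2], "]")
  structure(list(subject_id = as.character(subject_id),
                 trial_id = as.character(trial_id),
                 signals = signals,
                 sampling_rates = sampling_rates,
                 valence = valence, arousal = arousal,
                 scale_bounds = scale_bounds),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat("<recording> subject", x$subject_id, "trial", x$trial_id, "\n")
  for (m in names(x$signals))
    cat(sprintf("  %s: %d ch x %d samples @ %g Hz\n", m,
                nrow(x$signals[[m]]), ncol(x$signals[[m]]),
                x$sampling_rates[[m]]))
  cat(sprintf("  valence %.2f, arousal %.2f on [%g, %g]\n",
              x$valence, x$arousal, x$scale_bounds[1], x$scale_bounds[2]))
  invisible(x)
}

#' Trial duration in seconds
#'
#' @param rec A [recording()].
#' @return Duration in seconds (minimum across modalities).
#' @export
recording_duration <- function(rec) {
  min(vapply(names(rec$signals), function(m)
    ncol(rec$signals[[m]]) / rec$sampling_rates[[m]], numeric(1)))
}

#' Map valence/arousal ratings to a quadrant label
#'
#' Splits the rating square at the scale midpoint `(min + max) / 2`: a rating
#' strictly above the midpoint is "high", otherwise "low" (a rating exactly at
#' the midpoint maps low, a deterministic tie rule). The threshold is
#' configurable because rating scales and neutral points vary between studies.
#'
#' @param valence,arousal Ratings within `bounds`.
#' @param bounds Length-2 numeric `(min, max)` of the rating scale.
#' @param threshold Split point; defaults to the scale midpoint.
#' @return One of `"HVHA"`, `"HVLA"`, `"LVHA"`, `"LVLA"`.
#' @examples
#' label_from_ratings(7, 8, c(1, 9))  # "HVHA"
#' label_from_ratings(5, 5, c(1, 9))  # midpoint ties map low: "LVLA"
#' @export
label_from_ratings <- function(valence, arousal, bounds = c(1, 9),
                               threshold = NULL) {
  stopifnot(length(bounds) == 2, bounds[1] < bounds[2])
  if (is.na(valence) || is.na(arousal))
    stop("label_from_ratings: missing rating")
  if (valence < bounds[1] || valence > bounds[2] ||
      arousal < bounds[1] || arousal > bounds[2])
    stop("label_from_ratings: rating outside bounds [", bounds[1], ", ",
         bounds[2], "]")
  if (is.null(threshold)) threshold <- mean(bounds)
  v <- if (valence > threshold) "HV" else "LV"
  a <- if (arousal > threshold) "HA" else "LA"
  paste0(v, a)
}

#' Label of a recording, or NA when unlabeled
#'
#' @param rec A [recording()].
#' @param threshold Optional split point passed to [label_from_ratings()].
#' @return Quadrant label string or `NA`.
#' @export
recording_label <- function(rec, threshold = NULL) {
  if (is.na(rec$valence) || is.na(rec$arousal)) return(NA_character_)
  label_from_ratings(rec$valence, rec$arousal, rec$scale_bounds, threshold)
}

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline in one validated list: the
#' segmentation window and hop (seconds), per-modality filter bands, the
#' wavelet and decomposition depth for the scalograms, the scalogram image
#' size, the autoencoder and classifier hyperparameters, the fold count and
#' the master seed.
#'
#' @param window_s,hop_s Window length and hop in seconds; `hop_s <= window_s`.
#' @param modalities Named list of [modality_spec()].
#' @param wavelet Wavelet name (see [wavelet_spec()]).
#' @param levels Decomposition depth.
#' @param scalogram_size Length-2 integer `(H, W)`.
#' @param sae Autoencoder hyperparameters, see [sae_config()]; a plain list of
#'   overrides is accepted.
#' @param classifiers List of classifier hyperparameters
#'   (`svm_cost`, `rf_trees`, `lstm_hidden`, `lstm_epochs`, `lstm_steps`,
#'   `tie_rule`).
#' @param k Number of cross-validation folds.
#' @param cv_mode `"stratified"` (segment-level, mirrors subject-mixing
#'   evaluation) or `"grouped"` (subject-disjoint folds).
#' @param filter_first Filter whole trials before segmentation (default) or
#'   segment first.
#' @param ica Apply ICA to EEG (default `TRUE`).
#' @param seed Master seed; every stochastic stage derives its seed from it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(window_s = 30, hop_s = 15,
                            modalities = default_modalities(),
                            wavelet = "db4", levels = 5,
                            scalogram_size = c(64, 64),
                            sae = list(), classifiers = list(),
                            k = 10, cv_mode = c("stratified", "grouped"),
                            filter_first = TRUE, ica = TRUE, seed = 1L) {
  cv_mode <- match.arg(cv_mode)
  if (hop_s > window_s)
    stop("pipeline_config: hop_s (", hop_s, ") must not exceed window_s (",
         window_s, ")")
  if (k < 2) stop("pipeline_config: k must be >= 2")
  cls <- utils::modifyList(
    list(svm_cost = 1, rf_trees = 100L, lstm_hidden = 32L,
         lstm_epochs = 30L, lstm_steps = 8L, lstm_lr = 1e-2,
         tie_rule = "lstm"),
    classifiers)
  structure(list(window_s = window_s, hop_s = hop_s, modalities = modalities,
                 wavelet = wavelet, levels = as.integer(levels),
                 scalogram_size = as.integer(scalogram_size),
                 sae = sae, classifiers = cls, k = as.integer(k),
                 cv_mode = cv_mode, filter_first = isTRUE(filter_first),
                 ica = isTRUE(ica), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as JSON or YAML
#'
#' The on-disk form is a plain named mapping; the file extension selects the
#' format (`.json` vs `.yml`/`.yaml`).
#'
#' @param config A [pipeline_config()].
#' @param path File path.
#' @return `read_config` returns a `pipeline_config`; `write_config` returns
#'   `path` invisibly.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$modalities <- lapply(x$modalities, unclass)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  mods <- lapply(x$modalities, function(m)
    modality_spec(m$name, m$n_channels, m$sampling_rate, as.numeric(m$band)))
  pipeline_config(window_s = x$window_s, hop_s = x$hop_s, modalities = mods,
                  wavelet = x$wavelet, levels = x$levels,
                  scalogram_size = as.integer(x$scalogram_size),
                  sae = as.list(x$sae), classifiers = as.list(x$classifiers),
                  k = x$k, cv_mode = x$cv_mode,
                  filter_first = x$filter_first, ica = x$ica, seed = x$seed)
}
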