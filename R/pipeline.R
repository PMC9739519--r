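obj_digest <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  # strip environments that serialize unstably
  writeBin(serialize(x, NULL, version = 2), f)
  unname(tools::md5sum(f))
}

#' Desk-scale pipeline configuration
#'
#' The configuration used by the package's worked example and acceptance
#' runs: 30 s windows with 15 s hop, db4 wavelet at 5 levels, 32x32
#' scalograms, a 3-block autoencoder (15/9/3 kernels, 8/16/32 filters,
#' 64-d bottleneck, 10 epochs) and 10-fold stratified cross-validation.
#' Sized so a full run completes in minutes on one CPU core; the
#' full-scale defaults of [pipeline_config()] and [sae_config()] remain
#' available for larger studies.
#'
#' @param seed Master seed.
#' @return A [pipeline_config()].
#' @export
desk_scale_config <- function(seed = 1L) {
  pipeline_config(
    scalogram_size = c(32L, 32L),
    sae = list(kernels = c(15L, 9L, 3L), filters = c(8L, 16L, 32L),
               bottleneck = 64L, epochs = 10L, batch_size = 16L,
               lr = 1e-3, lambda = 1e-4, dropout = 0.1),
    classifiers = list(lstm_steps = 4L, lstm_epochs = 80L),
    k = 10L, seed = seed)
}

#' Run the full emotion-charting pipeline
#'
#' Synthesize or accept recordings, preprocess (bandpass, ICA, segmentation),
#' build per-channel scalograms, then cross-validate: within every fold the
#' autoencoder is trained unsupervised on the training segments only,
#' bottleneck features are extracted, the SVM/RF/LSTM ensemble is trained on
#' the training features and evaluated on the held-out fold. Returns the
#' pooled evaluation together with a run manifest recording the
#' configuration digest, per-stage output digests and fit lineage, which
#' makes the no-test-leakage property checkable after the fact.
#'
#' @param config A [pipeline_config()] (or a path to one written with
#'   [write_config()]).
#' @param recordings Optional list of [recording()] objects; when `NULL`, a
#'   synthetic dataset is generated from `preset`.
#' @param preset [synth_preset()] name used when `recordings` is `NULL`.
#' @param n_subjects,trials_per_subject Synthetic dataset size.
#' @param verbose Log stage progress to stderr.
#' @return An object of class `pipeline_run`: `report` (an `eval_report`)
#'   and `manifest`.
#' @export
run_pipeline <- function(config = desk_scale_config(), recordings = NULL,
                         preset = "easy", n_subjects = 8L,
                         trials_per_subject = 4L, verbose = FALSE) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message("[emochart] ", ...)
  t0 <- Sys.time()
  manifest <- list(
    created = format(t0, "%Y-%m-%d %H:%M:%S"),
    package_version = as.character(utils::packageVersion("emochart")),
    seed = config$seed,
    config_digest = obj_digest(config),
    stages = list())
  stage <- function(name, value) {
    manifest$stages[[name]] <<- obj_digest(value)
    say(name, " done (digest ", substr(manifest$stages[[name]], 1, 8), ")")
    value
  }

  if (is.null(recordings)) {
    say("synthesizing ", preset, " dataset: ", n_subjects, " subjects x ",
        trials_per_subject, " trials")
    spec <- synth_preset(preset, n_subjects = n_subjects,
                         trials_per_subject = trials_per_subject,
                         seed = config$seed)
    recordings <- stage("synth", generate_dataset(spec))
  } else {
    manifest$stages[["input"]] <- obj_digest(
      lapply(recordings, function(r) r$signals))
  }

  labeled <- !vapply(recordings, function(r)
    is.na(r$valence) || is.na(r$arousal), logical(1))
  if (!all(labeled)) {
    say("excluding ", sum(!labeled), " unlabeled recording(s)")
    recordings <- recordings[labeled]
  }

  segs <- stage("preprocess", bind_segment_sets(
    lapply(recordings, preprocess_recording, config = config)))
  scal <- stage("scalograms", segment_scalograms(segs, config))
  report <- crossval_scalograms(scal, config)
  manifest$stages[["evaluate"]] <- obj_digest(report$predictions)
  manifest$fold_lineage <- report$fold_manifest
  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  say(sprintf("pooled ensemble accuracy %.3f (%.1f s)", report$accuracy,
              manifest$elapsed_s))
  structure(list(report = report, manifest = manifest, config = config),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run> seed", x$config$seed, "\n")
  print(x$report)
  invisible(x)
}

#' Check a run manifest for train/test leakage
#'
#' Verifies, from the recorded lineage, that no segment used to fit the
#' autoencoder or any classifier in a fold appears in that fold's test set.
#'
#' @param run A `pipeline_run` (or its manifest).
#' @return `TRUE` invisibly; errors describing the offending fold and
#'   segment ids otherwise.
#' @export
assert_no_leakage <- function(run) {
  man <- if (inherits(run, "pipeline_run")) run$manifest else run
  for (f in seq_along(man$fold_lineage)) {
    ln <- man$fold_lineage[[f]]
    bad_sae <- intersect(ln$sae_fit_ids, ln$test_ids)
    bad_clf <- intersect(ln$classifier_fit_ids, ln$test_ids)
    if (length(bad_sae) || length(bad_clf))
      stop("leakage in fold ", f, ": ",
           paste(unique(c(bad_sae, bad_clf)), collapse = ", "),
           " used for fitting and testing")
  }
  invisible(TRUE)
}
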