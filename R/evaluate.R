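#' k-fold cross-validation splits
#'
#' Stratified mode shuffles within each class and deals segments to folds
#' round-robin, so fold class proportions match the data within one segment;
#' grouped mode assigns whole subjects to folds, never splitting a subject
#' across train and test. Both are deterministic under `seed`.
#'
#' @param labels Character vector of segment labels.
#' @param k Number of folds (default 10).
#' @param mode `"stratified"` or `"grouped"`.
#' @param seed Shuffle seed.
#' @param subjects Subject id per segment (required for grouped mode).
#' @return List of `k` lists with `train` and `test` index vectors
#'   (disjoint, exhaustive).
#' @export
kfold_split <- function(labels, k = 10L, mode = c("stratified", "grouped"),
                        seed = 1L, subjects = NULL) {
  mode <- match.arg(mode)
  n <- length(labels)
  fold_of <- integer(n)
  if (mode == "stratified") {
    cnt <- table(labels)
    if (any(cnt < k))
      stop("kfold_split: stratified mode needs at least k = ", k,
           " segments per class; class ",
           names(cnt)[which.min(cnt)], " has ", min(cnt))
    withr::with_seed(seed, {
      for (cl in names(cnt)) {
        idx <- sample(which(labels == cl))
        fold_of[idx] <- rep_len(seq_len(k), length(idx))
      }
    })
  } else {
    if (is.null(subjects))
      stop("kfold_split: grouped mode needs subject ids")
    subj <- unique(subjects)
    if (length(subj) < k)
      stop("kfold_split: grouped mode needs at least k = ", k,
           " subjects, got ", length(subj))
    withr::with_seed(seed, {
      subj <- sample(subj)
      grp <- rep_len(seq_len(k), length(subj))
      fold_of <- grp[match(subjects, subj)]
    })
  }
  lapply(seq_len(k), function(f)
    list(train = which(fold_of != f), test = which(fold_of == f)))
}

#' Confusion matrix over the four quadrants
#'
#' @param true,pred Character label vectors of equal length.
#' @return 4x4 integer matrix, rows = true, columns = predicted, class
#'   order `HVHA, HVLA, LVHA, LVLA`.
#' @export
confusion_matrix <- function(true, pred) {
  if (length(true) != length(pred))
    stop("confusion_matrix: length mismatch (", length(true), " vs ",
         length(pred), ")")
  lv <- quadrant_levels()
  table(factor(true, lv), factor(pred, lv), dnn = c("true", "predicted"))
}

#' Accuracy and one-vs-all sensitivity/specificity
#'
#' Overall accuracy is the multiclass trace over total. Each class is then
#' binarized one-vs-all: `TP` the diagonal cell, `FN` the rest of its row,
#' `FP` the rest of its column, `TN` the remainder;
#' sensitivity `TP/(TP+FN)` and specificity `TN/(TN+FP)`. A zero
#' denominator yields `NA` (undefined), never 0.
#'
#' @param true,pred Character label vectors of equal length.
#' @return An object of class `eval_fragment`: `confusion`, `accuracy`,
#'   `per_class` (data frame with tp/fn/fp/tn, sensitivity, specificity),
#'   `n`.
#' @export
score <- function(true, pred) {
  cm <- confusion_matrix(true, pred)
  n <- sum(cm)
  lv <- quadrant_levels()
  per <- do.call(rbind, lapply(seq_along(lv), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- n - tp - fn - fp
    data.frame(class = lv[i], tp = tp, fn = fn, fp = fp, tn = tn,
               sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  structure(list(confusion = cm, accuracy = sum(diag(cm)) / n,
                 per_class = per, n = n), class = "eval_fragment")
}

#' @export
print.eval_fragment <- function(x, ...) {
  cat(sprintf("<eval_fragment> n = %d, accuracy = %.3f\n", x$n, x$accuracy))
  print(x$confusion)
  invisible(x)
}

ablation_prep_levels <- c("no-preprocess", "bandpass", "bandpass+ica")
ablation_feat_levels <- c("scalogram", "autoencoder", "stacked-autoencoder")
ablation_clf_levels <- c("cnn", "rf", "svm", "lstm", "ensemble")

parse_variant <- function(v) {
  parts <- strsplit(v, "/", fixed = TRUE)[[1]]
  ok <- length(parts) == 3 && parts[1] %in% ablation_prep_levels &&
    parts[2] %in% ablation_feat_levels && parts[3] %in% ablation_clf_levels
  if (!ok)
    stop("unknown ablation variant '", v, "'; variants are ",
         "\"<preprocess>/<features>/<classifier>\" with preprocess in {",
         paste(ablation_prep_levels, collapse = ", "), "}, features in {",
         paste(ablation_feat_levels, collapse = ", "), "}, classifier in {",
         paste(ablation_clf_levels, collapse = ", "), "}")
  if (parts[2] == "scalogram" && parts[3] != "cnn")
    stop("variant '", v, "': classifier '", parts[3],
         "' needs extracted feature vectors; only the cnn head runs on raw ",
         "scalograms")
  list(prep = parts[1], feat = parts[2], clf = parts[3])
}

# Cross-validated evaluation of one pipeline configuration on a scalogram
# batch. The autoencoder (when used) and all classifiers are fitted on the
# training folds only; features for the test fold come from the
# training-fold autoencoder. Lineage of every fit is recorded.
crossval_scalograms <- function(scal, config, feat = "stacked-autoencoder",
                                clf = "ensemble", folds = NULL) {
  labels <- scal$labels
  keep <- !is.na(labels)
  if (!all(keep)) {
    scal$x <- scal$x[, , , keep, drop = FALSE]
    scal$labels <- labels <- labels[keep]
    scal$provenance <- scal$provenance[keep, , drop = FALSE]
  }
  if (is.null(folds))
    folds <- kfold_split(labels, config$k, config$cv_mode, config$seed,
                         subjects = scal$provenance$subject_id)
  n <- length(labels)
  seg_ids <- sprintf("%s:%s:%gs", scal$provenance$subject_id,
                     scal$provenance$trial_id, scal$provenance$start_s)
  pred <- data.frame(voted = rep(NA_character_, n), svm = NA_character_,
                     rf = NA_character_, lstm = NA_character_,
                     fold = NA_integer_, stringsAsFactors = FALSE)
  fold_frags <- vector("list", length(folds))
  manifest <- vector("list", length(folds))
  d <- dim(scal$x)

  sae_over <- config$sae
  base_sae <- list(input_planes = d[3], size = d[1:2],
                   seed = config$seed)
  for (f in seq_along(folds)) {
    tr <- folds[[f]]$train; te <- folds[[f]]$test
    fit_ids <- seg_ids[tr]
    if (feat == "scalogram") {
      features <- NULL
    } else {
      ov <- utils::modifyList(base_sae, sae_over)
      if (feat == "autoencoder") {
        ov$kernels <- (if (is.null(ov$kernels)) c(15L, 9L, 3L) else
                         ov$kernels)[1]
        ov$filters <- (if (is.null(ov$filters)) c(16L, 32L, 64L) else
                         ov$filters)[1]
      }
      scfg <- do.call(sae_config, ov)
      sae <- sae_train(scfg, scal$x[, , , tr, drop = FALSE])
      features <- extract_features(sae, scal$x)
    }
    opts <- config$classifiers
    seed_f <- config$seed + f
    if (clf == "ensemble") {
      bundle <- train_classifier_bundle(features[tr, , drop = FALSE],
                                        labels[tr], opts, seed = seed_f)
      pv <- predict(bundle, features[te, , drop = FALSE])
      pred$voted[te] <- pv$voted
      pred$svm[te] <- pv$svm; pred$rf[te] <- pv$rf; pred$lstm[te] <- pv$lstm
    } else if (clf == "cnn") {
      if (is.null(features)) {
        m <- train_cnn_head(scal$x[, , , tr, drop = FALSE], labels[tr],
                            seed = seed_f)
        pred$voted[te] <- predict(m, scal$x[, , , te, drop = FALSE])
      } else {
        m <- train_dense_head(features[tr, , drop = FALSE], labels[tr],
                              seed = seed_f)
        pred$voted[te] <- predict(m, features[te, , drop = FALSE])
      }
    } else {
      m <- switch(clf,
        svm = train_svm(features[tr, , drop = FALSE], labels[tr],
                        cost = opts$svm_cost, seed = seed_f),
        rf = train_rf(features[tr, , drop = FALSE], labels[tr],
                      n_trees = opts$rf_trees, seed = seed_f),
        lstm = train_lstm(features[tr, , drop = FALSE], labels[tr],
                          hidden_dim = opts$lstm_hidden,
                          steps = opts$lstm_steps,
                          epochs = opts$lstm_epochs,
                          lr = if (is.null(opts$lstm_lr)) 1e-2 else
                            opts$lstm_lr,
                          seed = seed_f))
      pred$voted[te] <- predict(m, features[te, , drop = FALSE])
    }
    pred$fold[te] <- f
    fold_frags[[f]] <- score(labels[te], pred$voted[te])
    manifest[[f]] <- list(
      sae_fit_ids = if (feat == "scalogram") character(0) else fit_ids,
      classifier_fit_ids = fit_ids,
      test_ids = seg_ids[te])
  }
  pooled <- score(labels, pred$voted)
  structure(list(accuracy = pooled$accuracy, confusion = pooled$confusion,
                 per_class = pooled$per_class, fold_reports = fold_frags,
                 folds = folds, predictions = cbind(
                   scal$provenance, true = labels, pred,
                   stringsAsFactors = FALSE),
                 fold_manifest = manifest, feat = feat, clf = clf,
                 k = length(folds), seed = config$seed),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> %s / %s: pooled accuracy %.3f over %d folds (n = %d)\n",
    x$feat, x$clf, x$accuracy, x$k, sum(x$confusion)))
  print(x$confusion)
  cat("per-class sensitivity:",
      paste(sprintf("%s %.2f", x$per_class$class, x$per_class$sensitivity),
            collapse = ", "), "\n")
  invisible(x)
}

#' Ablation harness over the preprocessing / feature / classifier ladder
#'
#' Evaluates named pipeline variants on the same recordings with shared
#' fold assignments and seed, so differences between rows are attributable
#' to the varied stage. Variant names are
#' `"<preprocess>/<features>/<classifier>"`, e.g.
#' `"no-preprocess/scalogram/cnn"` or
#' `"bandpass+ica/stacked-autoencoder/ensemble"`.
#'
#' @param recordings List of [recording()] objects.
#' @param config A [pipeline_config()].
#' @param variants Character vector of variant names.
#' @return Named list of `eval_report`s, one per variant, with the shared
#'   fold list as attribute `"folds"`.
#' @export
run_ablation <- function(recordings, config = pipeline_config(),
                         variants) {
  parsed <- lapply(variants, parse_variant)
  names(parsed) <- variants
  scal_cache <- list()
  get_scal <- function(prep) {
    if (!is.null(scal_cache[[prep]])) return(scal_cache[[prep]])
    segs <- bind_segment_sets(lapply(recordings, function(r)
      preprocess_recording(r, config,
                           bandpass_on = prep != "no-preprocess",
                           ica_on = prep == "bandpass+ica")))
    sc <- segment_scalograms(segs, config)
    scal_cache[[prep]] <<- sc
    sc
  }
  first <- get_scal(parsed[[1]]$prep)
  keep <- !is.na(first$labels)
  folds <- kfold_split(first$labels[keep], config$k, config$cv_mode,
                       config$seed,
                       subjects = first$provenance$subject_id[keep])
  out <- lapply(parsed, function(v)
    crossval_scalograms(get_scal(v$prep), config, feat = v$feat,
                        clf = v$clf, folds = folds))
  attr(out, "folds") <- folds
  out
}
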