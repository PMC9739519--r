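# SVM / random-forest members of the ensemble, and majority voting.
# Both trainers canonicalise the order of the training rows (sort by label,
# then lexicographically by feature values) before fitting, so the fitted
# model depends on the training *set*, not on the order it arrived in.

canonical_order <- function(features, labels) {
  do.call(order, c(list(as.character(labels)),
                   lapply(seq_len(ncol(features)), function(j) features[, j])))
}

#' Train a linear one-vs-rest SVM on bottleneck features
#'
#' Four binary linear-kernel SVMs (one per quadrant against the rest);
#' prediction takes the class with the largest oriented decision value.
#'
#' @param features `n x d` numeric matrix.
#' @param labels Character quadrant labels.
#' @param cost Soft-margin cost C (default 1).
#' @param seed Kept for interface symmetry; the linear SVM fit is
#'   deterministic.
#' @return An object of class `ovr_svm`.
#' @export
train_svm <- function(features, labels, cost = 1, seed = 1L) {
  features <- as.matrix(features)
  classes <- quadrant_levels()
  check_training_labels(labels, classes)
  ord <- canonical_order(features, labels)
  features <- features[ord, , drop = FALSE]
  labels <- as.character(labels)[ord]
  models <- lapply(classes, function(cl) {
    y <- factor(ifelse(labels == cl, cl, "rest"), levels = c(cl, "rest"))
    m <- e1071::svm(features, y, kernel = "linear", cost = cost,
                    scale = TRUE, decision.values = TRUE)
    dv <- attr(predict(m, features, decision.values = TRUE),
               "decision.values")[, 1]
    orient <- if (mean(dv[y == cl]) >= mean(dv[y != cl])) 1 else -1
    list(svm = m, orient = orient)
  })
  names(models) <- classes
  structure(list(models = models, classes = classes, cost = cost),
            class = "ovr_svm")
}

#' @export
predict.ovr_svm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  dv <- vapply(object$classes, function(cl) {
    m <- object$models[[cl]]
    m$orient * attr(predict(m$svm, newdata, decision.values = TRUE),
                    "decision.values")[, 1]
  }, numeric(nrow(newdata)))
  if (is.null(dim(dv))) dv <- matrix(dv, 1)
  object$classes[max.col(dv, ties.method = "first")]
}

#' Train a random forest on bottleneck features
#'
#' Seeded bootstrap: predictions are reproducible under a fixed seed and
#' invariant to the order of the training rows.
#'
#' @param features `n x d` numeric matrix.
#' @param labels Character quadrant labels.
#' @param n_trees Number of trees (default 100).
#' @param seed Bootstrap seed.
#' @return An object of class `rf_model` wrapping
#'   [randomForest::randomForest()].
#' @export
train_rf <- function(features, labels, n_trees = 100L, seed = 1L) {
  features <- as.matrix(features)
  classes <- quadrant_levels()
  labels <- as.character(labels)
  if (length(unique(labels)) == 1) {
    # degenerate single-class input: the forest has nothing to split on
    return(structure(list(rf = NULL, constant = labels[1], classes = classes),
                     class = "rf_model"))
  }
  check_training_labels(labels, classes)
  ord <- canonical_order(features, labels)
  fit <- withr::with_seed(seed, randomForest::randomForest(
    x = features[ord, , drop = FALSE],
    y = factor(labels[ord], levels = intersect(classes, labels)),
    ntree = n_trees))
  structure(list(rf = fit, classes = classes), class = "rf_model")
}

#' @export
predict.rf_model <- function(object, newdata, ...) {
  if (is.null(object$rf))
    return(rep(object$constant, nrow(as.matrix(newdata))))
  as.character(predict(object$rf, as.matrix(newdata)))
}

#' Combine three classifier votes into an ensemble prediction
#'
#' A label voted by at least two of the SVM, RF and LSTM wins. On a
#' three-way disagreement the fallback is the LSTM's label (`tie_rule =
#' "lstm"`, the strongest standalone member) with `tie_broken = TRUE`;
#' `tie_rule = "svm"` or `"rf"` select the other members instead.
#'
#' @param p_svm,p_rf,p_lstm Equal-length character vectors of quadrant
#'   labels.
#' @param tie_rule Which member's label to fall back to on a three-way tie.
#' @return Data frame with per-classifier labels, `voted`, `votes` (count
#'   for the winning label) and `tie_broken`.
#' @export
majority_vote <- function(p_svm, p_rf, p_lstm,
                          tie_rule = c("lstm", "svm", "rf")) {
  tie_rule <- match.arg(tie_rule)
  n <- length(p_svm)
  stopifnot(length(p_rf) == n, length(p_lstm) == n)
  all_lab <- c(p_svm, p_rf, p_lstm)
  bad <- setdiff(unique(all_lab), quadrant_levels())
  if (length(bad))
    stop("majority_vote: label(s) outside the quadrant set: ",
         paste(bad, collapse = ", "))
  voted <- character(n); votes <- integer(n); tie <- logical(n)
  for (i in seq_len(n)) {
    tb <- table(c(p_svm[i], p_rf[i], p_lstm[i]))
    if (max(tb) >= 2) {
      voted[i] <- names(tb)[which.max(tb)]
      votes[i] <- max(tb)
    } else {
      voted[i] <- switch(tie_rule, lstm = p_lstm[i], svm = p_svm[i],
                         rf = p_rf[i])
      votes[i] <- 1L
      tie[i] <- TRUE
    }
  }
  data.frame(svm = p_svm, rf = p_rf, lstm = p_lstm, voted = voted,
             votes = votes, tie_broken = tie, stringsAsFactors = FALSE)
}

#' Train the full SVM + RF + LSTM ensemble
#'
#' All three members are trained on the identical feature/label set.
#'
#' @param features `n x d` feature matrix.
#' @param labels Character quadrant labels.
#' @param opts Classifier hyperparameters (see [pipeline_config()]'s
#'   `classifiers` element).
#' @param seed Seed shared by the members.
#' @return An object of class `classifier_bundle`.
#' @export
train_classifier_bundle <- function(features, labels,
                                    opts = pipeline_config()$classifiers,
                                    seed = 1L) {
  structure(list(
    svm = train_svm(features, labels, cost = opts$svm_cost, seed = seed),
    rf = train_rf(features, labels, n_trees = opts$rf_trees, seed = seed),
    lstm = train_lstm(features, labels, hidden_dim = opts$lstm_hidden,
                      steps = opts$lstm_steps, epochs = opts$lstm_epochs,
                      lr = if (is.null(opts$lstm_lr)) 1e-2 else opts$lstm_lr,
                      seed = seed),
    tie_rule = opts$tie_rule, fitted = TRUE, seed = seed),
    class = "classifier_bundle")
}

#' @export
predict.classifier_bundle <- function(object, newdata, ...) {
  majority_vote(predict(object$svm, newdata),
                predict(object$rf, newdata),
                predict(object$lstm, newdata),
                tie_rule = object$tie_rule)
}
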