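sigmoid <- function(x) 1 / (1 + exp(-x))

#' One LSTM cell step, reference gate arithmetic
#'
#' Computes the forget, input and output gates and the cell/hidden update
#' exactly as the standard gate equations prescribe:
#' `y_t = sigmoid(a_t A_f + h_{t-1} H_f)` (forget),
#' `I_t = sigmoid(a_t A_i + h_{t-1} H_i)` (input),
#' `n_t = tanh(a_t U_c + h_{t-1} H_c)` (candidate),
#' `c_t = y_t * c_{t-1} + I_t * n_t`,
#' `o_t = sigmoid(a_t A_o + h_{t-1} H_o)`,
#' `h_t = o_t * tanh(c_t)`, all elementwise. Biases default to zero
#' (the gate equations carry none); trained cells may supply them.
#'
#' @param p Parameter list with input weights `A_f`, `A_i`, `U_c`, `A_o`
#'   (each `input_dim x hidden_dim`), recurrent weights `H_f`, `H_i`, `H_c`,
#'   `H_o` (each `hidden_dim x hidden_dim`) and optional biases `b_f`,
#'   `b_i`, `b_c`, `b_o`.
#' @param a_t Input vector (length `input_dim`).
#' @param h_prev,c_prev Previous hidden and cell state (length
#'   `hidden_dim`).
#' @return List with `h`, `c` and the gate traces `y` (forget), `I`
#'   (input), `n` (candidate), `o` (output).
#' @export
lstm_cell_step <- function(p, a_t, h_prev, c_prev) {
  hd <- ncol(p$A_f)
  stopifnot(length(a_t) == nrow(p$A_f), length(h_prev) == hd,
            length(c_prev) == hd)
  bz <- function(b) if (is.null(b)) 0 else b
  a_t <- matrix(a_t, 1); h_prev <- matrix(h_prev, 1)
  y <- sigmoid(a_t %*% p$A_f + h_prev %*% p$H_f + bz(p$b_f))
  I <- sigmoid(a_t %*% p$A_i + h_prev %*% p$H_i + bz(p$b_i))
  n <- tanh(a_t %*% p$U_c + h_prev %*% p$H_c + bz(p$b_c))
  o <- sigmoid(a_t %*% p$A_o + h_prev %*% p$H_o + bz(p$b_o))
  c_t <- y * c_prev + I * n
  h_t <- o * tanh(c_t)
  list(h = drop(h_t), c = drop(c_t), y = drop(y), I = drop(I),
       n = drop(n), o = drop(o))
}

lstm_init <- function(input_dim, hidden_dim, n_classes, seed,
                      train_bias = TRUE) {
  withr::with_seed(seed, {
    mk <- function(a, b) matrix(rnorm(a * b, sd = 1 / sqrt(a)), a, b)
    p <- list(A_f = mk(input_dim, hidden_dim), A_i = mk(input_dim, hidden_dim),
              U_c = mk(input_dim, hidden_dim), A_o = mk(input_dim, hidden_dim),
              H_f = mk(hidden_dim, hidden_dim), H_i = mk(hidden_dim, hidden_dim),
              H_c = mk(hidden_dim, hidden_dim), H_o = mk(hidden_dim, hidden_dim),
              W_out = mk(hidden_dim, n_classes), b_out = numeric(n_classes))
    if (train_bias) {
      p$b_f <- rep(1, hidden_dim)  # standard positive forget-gate bias
      p$b_i <- numeric(hidden_dim); p$b_c <- numeric(hidden_dim)
      p$b_o <- numeric(hidden_dim)
    }
    p
  })
}

# batched forward over a sequence: X is B x input_dim x steps
lstm_forward <- function(p, X) {
  B <- dim(X)[1]; steps <- dim(X)[3]; hd <- ncol(p$A_f)
  bz <- function(b) if (is.null(b)) 0 else matrix(b, B, hd, byrow = TRUE)
  h <- matrix(0, B, hd); cst <- matrix(0, B, hd)
  cache <- vector("list", steps)
  for (t in seq_len(steps)) {
    a <- X[, , t, drop = FALSE]; dim(a) <- dim(X)[1:2]
    y <- sigmoid(a %*% p$A_f + h %*% p$H_f + bz(p$b_f))
    I <- sigmoid(a %*% p$A_i + h %*% p$H_i + bz(p$b_i))
    n <- tanh(a %*% p$U_c + h %*% p$H_c + bz(p$b_c))
    o <- sigmoid(a %*% p$A_o + h %*% p$H_o + bz(p$b_o))
    c_new <- y * cst + I * n
    tc <- tanh(c_new)
    h_new <- o * tc
    cache[[t]] <- list(a = a, h_prev = h, c_prev = cst, y = y, I = I,
                       n = n, o = o, tc = tc)
    h <- h_new; cst <- c_new
  }
  logits <- sweep(h %*% p$W_out, 2, p$b_out, "+")
  list(logits = logits, h = h, cache = cache)
}

lstm_backward <- function(p, fw, dlogits) {
  steps <- length(fw$cache)
  g <- lapply(p, function(x) x * 0)
  g$W_out <- crossprod(fw$h, dlogits)
  g$b_out <- colSums(dlogits)
  dh <- dlogits %*% t(p$W_out)
  dc <- matrix(0, nrow(dh), ncol(dh))
  has_bias <- !is.null(p$b_f)
  for (t in rev(seq_len(steps))) {
    cc <- fw$cache[[t]]
    do_ <- dh * cc$tc
    dc <- dc + dh * cc$o * (1 - cc$tc^2)
    dy <- dc * cc$c_prev
    dI <- dc * cc$n
    dn <- dc * cc$I
    dc_prev <- dc * cc$y
    dzy <- dy * cc$y * (1 - cc$y)
    dzi <- dI * cc$I * (1 - cc$I)
    dzn <- dn * (1 - cc$n^2)
    dzo <- do_ * cc$o * (1 - cc$o)
    g$A_f <- g$A_f + crossprod(cc$a, dzy)
    g$A_i <- g$A_i + crossprod(cc$a, dzi)
    g$U_c <- g$U_c + crossprod(cc$a, dzn)
    g$A_o <- g$A_o + crossprod(cc$a, dzo)
    g$H_f <- g$H_f + crossprod(cc$h_prev, dzy)
    g$H_i <- g$H_i + crossprod(cc$h_prev, dzi)
    g$H_c <- g$H_c + crossprod(cc$h_prev, dzn)
    g$H_o <- g$H_o + crossprod(cc$h_prev, dzo)
    if (has_bias) {
      g$b_f <- g$b_f + colSums(dzy); g$b_i <- g$b_i + colSums(dzi)
      g$b_c <- g$b_c + colSums(dzn); g$b_o <- g$b_o + colSums(dzo)
    }
    dh <- dzy %*% t(p$H_f) + dzi %*% t(p$H_i) + dzn %*% t(p$H_c) +
      dzo %*% t(p$H_o)
    dc <- dc_prev
  }
  g
}

feature_sequence <- function(features, steps) {
  n <- nrow(features); d <- ncol(features)
  per <- ceiling(d / steps)
  if (per * steps != d) {
    pad <- matrix(0, n, per * steps - d)
    features <- cbind(features, pad)
  }
  X <- array(0, c(n, per, steps))
  for (t in seq_len(steps))
    X[, , t] <- features[, ((t - 1) * per + 1):(t * per), drop = FALSE]
  X
}

#' Train the LSTM classifier on bottleneck features
#'
#' Each static feature vector is unrolled into a short sequence
#' (`steps` timesteps of `ceiling(dim/steps)` features, zero-padded when
#' uneven), run through a single LSTM cell with `hidden_dim` units, and the
#' final hidden state feeds a softmax over the four quadrants. Training is
#' full-batch Adam, so the fit is deterministic under a fixed seed.
#'
#' @param features `n x d` feature matrix.
#' @param labels Character vector of quadrant labels.
#' @param hidden_dim LSTM width (default 32).
#' @param steps Sequence length the feature vector is reshaped into.
#' @param epochs,lr Training schedule.
#' @param seed Seed for the initialization.
#' @return An object of class `lstm_model`.
#' @export
train_lstm <- function(features, labels, hidden_dim = 32L, steps = 8L,
                       epochs = 30L, lr = 1e-2, seed = 1L) {
  classes <- quadrant_levels()
  check_training_labels(labels, classes)
  y <- match(labels, classes)
  X <- feature_sequence(as.matrix(features), steps)
  p <- lstm_init(dim(X)[2], hidden_dim, length(classes), seed)
  opt <- adam_init(p)
  hist <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    fw <- lstm_forward(p, X)
    sx <- softmax_xent(fw$logits, y)
    g <- lstm_backward(p, fw, sx$dlogits)
    st <- adam_step(opt, p, g, lr = lr)
    p <- st$params; opt <- st$state
    hist[ep] <- sx$loss
  }
  structure(list(params = p, steps = steps, hidden_dim = hidden_dim,
                 classes = classes, d = ncol(features),
                 loss_history = hist, seed = seed),
            class = "lstm_model")
}

#' @export
predict.lstm_model <- function(object, newdata, type = c("class", "prob"),
                               ...) {
  type <- match.arg(type)
  X <- feature_sequence(as.matrix(newdata), object$steps)
  fw <- lstm_forward(object$params, X)
  pr <- softmax(fw$logits)
  colnames(pr) <- object$classes
  if (type == "prob") pr else object$classes[max.col(pr, ties.method = "first")]
}

check_training_labels <- function(labels, classes) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), classes)
  if (length(bad))
    stop("labels outside the quadrant set: ", paste(bad, collapse = ", "))
  missing <- setdiff(classes, unique(labels))
  if (length(missing))
    stop("class(es) absent from training data: ",
         paste(missing, collapse = ", "))
  cnt <- table(factor(labels, classes))
  if (any(cnt < 2))
    stop("need at least 2 samples per class; short: ",
         paste(names(cnt)[cnt < 2], collapse = ", "))
  invisible(labels)
}
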