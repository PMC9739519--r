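test_that("lstm_cell_step matches its closed forms at zero weights", {
  mk0 <- function(d, h) matrix(0, d, h)
  p0 <- list(A_f = mk0(2, 3), A_i = mk0(2, 3), U_c = mk0(2, 3),
             A_o = mk0(2, 3), H_f = mk0(3, 3), H_i = mk0(3, 3),
             H_c = mk0(3, 3), H_o = mk0(3, 3))
  st <- lstm_cell_step(p0, c(1, 2), numeric(3), numeric(3))
  expect_equal(st$y, rep(0.5, 3))   # sigmoid(0)
  expect_equal(st$I, rep(0.5, 3))
  expect_equal(st$o, rep(0.5, 3))
  expect_equal(st$n, rep(0, 3))     # tanh(0)
  expect_equal(st$c, rep(0, 3))
  expect_equal(st$h, rep(0, 3))
})

test_that("lstm_cell_step matches an independent scalar oracle", {
  p1 <- list(A_f = matrix(1), A_i = matrix(1), U_c = matrix(1),
             A_o = matrix(1), H_f = matrix(0), H_i = matrix(0),
             H_c = matrix(0), H_o = matrix(0))
  s <- lstm_cell_step(p1, 0.5, 0, 1)
  # scalar oracle computed independently from the gate definitions
  sg <- 1 / (1 + exp(-0.5))
  nn <- tanh(0.5)
  cc <- sg * 1 + sg * nn
  hh <- sg * tanh(cc)
  expect_equal(s$y, sg, tolerance = 1e-10)
  expect_equal(s$I, sg, tolerance = 1e-10)
  expect_equal(s$o, sg, tolerance = 1e-10)
  expect_equal(s$n, nn, tolerance = 1e-10)
  expect_equal(s$c, cc, tolerance = 1e-10)
  expect_equal(s$h, hh, tolerance = 1e-10)
  expect_equal(round(c(s$y, s$n, s$c, s$h), 5),
               c(0.62246, 0.46212, 0.91011, 0.44891))
  # saturated forget gate with closed input gate leaves the cell unchanged
  psat <- list(A_f = matrix(1e3), A_i = matrix(-1e3), U_c = matrix(1),
               A_o = matrix(1), H_f = matrix(0), H_i = matrix(0),
               H_c = matrix(0), H_o = matrix(0))
  ssat <- lstm_cell_step(psat, 1, 0, 0.73)
  expect_equal(ssat$y, 1)
  expect_equal(ssat$I, 0)
  expect_equal(ssat$c, 0.73)
})

test_that("gate activations stay in range over random draws", {
  withr::with_seed(12, {
    for (i in 1:200) {
      d <- sample(1:4, 1); h <- sample(1:5, 1)
      mk <- function(a, b) matrix(rnorm(a * b, sd = 2), a, b)
      p <- list(A_f = mk(d, h), A_i = mk(d, h), U_c = mk(d, h),
                A_o = mk(d, h), H_f = mk(h, h), H_i = mk(h, h),
                H_c = mk(h, h), H_o = mk(h, h))
      st <- lstm_cell_step(p, rnorm(d), rnorm(h), rnorm(h))
      # mathematically open intervals; saturation may touch the bounds in
      # floating point, so the closed interval is asserted
      expect_true(all(st$y >= 0 & st$y <= 1))
      expect_true(all(st$I >= 0 & st$I <= 1))
      expect_true(all(st$o >= 0 & st$o <= 1))
      expect_true(all(st$n >= -1 & st$n <= 1))
    }
  })
})

test_that("trained LSTM separates separable features and is deterministic", {
  sf <- separable_features(n_per_class = 30, seed = 3)
  m <- train_lstm(sf$features, sf$labels, hidden_dim = 16L, steps = 4L,
                  epochs = 40L, seed = 5)
  expect_gte(mean(predict(m, sf$features) == sf$labels), 0.95)
  m2 <- train_lstm(sf$features, sf$labels, hidden_dim = 16L, steps = 4L,
                   epochs = 40L, seed = 5)
  expect_identical(predict(m, sf$features), predict(m2, sf$features))
  # the batched training cell agrees with the reference single-step cell
  X <- emochart:::feature_sequence(sf$features[1:2, , drop = FALSE], 4L)
  fw <- emochart:::lstm_forward(m$params, X)
  h <- numeric(16); cs <- numeric(16)
  for (t in 1:4) {
    r <- lstm_cell_step(m$params, X[1, , t], h, cs)
    h <- r$h; cs <- r$c
  }
  expect_equal(h, fw$h[1, ], tolerance = 1e-6)
  # a class missing from training is named in the error
  keep <- sf$labels != "LVHA"
  expect_error(train_lstm(sf$features[keep, ], sf$labels[keep]), "LVHA")
})

test_that("one-vs-rest linear SVM and seeded RF behave as contracted", {
  sf <- separable_features(n_per_class = 20, d = 2, seed = 4, shift = 4)
  sv <- train_svm(sf$features, sf$labels)
  expect_equal(mean(predict(sv, sf$features) == sf$labels), 1.0)
  rf <- train_rf(sf$features, sf$labels, seed = 9)
  # permuting training order with a fixed seed leaves predictions unchanged
  withr::with_seed(1, perm <- sample(nrow(sf$features)))
  rf2 <- train_rf(sf$features[perm, ], sf$labels[perm], seed = 9)
  expect_identical(predict(rf, sf$features), predict(rf2, sf$features))
  sv2 <- train_svm(sf$features[perm, ], sf$labels[perm])
  expect_identical(predict(sv, sf$features), predict(sv2, sf$features))
  # RF on single-class data always predicts that class
  one <- matrix(rnorm(40), 20)
  rf1 <- train_rf(one, rep("HVLA", 20), seed = 2)
  expect_true(all(predict(rf1, one) == "HVLA"))
})

test_that("majority vote matches a brute-force count on all 64 triples", {
  lv <- quadrant_levels()
  triples <- expand.grid(svm = lv, rf = lv, lstm = lv,
                         stringsAsFactors = FALSE)
  got <- majority_vote(triples$svm, triples$rf, triples$lstm)
  for (i in seq_len(nrow(triples))) {
    counts <- table(factor(unlist(triples[i, ]), lv))  # brute-force count
    if (max(counts) >= 2) {
      expect_equal(got$voted[i], names(counts)[which.max(counts)])
      expect_false(got$tie_broken[i])
      expect_equal(got$votes[i], as.integer(max(counts)))
    } else {
      expect_equal(got$voted[i], triples$lstm[i])   # LSTM tie-break
      expect_true(got$tie_broken[i])
    }
    # the winner always received at least one vote
    expect_true(got$voted[i] %in% unlist(triples[i, ]))
  }
  # voting is symmetric in the SVM/RF slots away from three-way ties
  sw <- majority_vote(triples$rf, triples$svm, triples$lstm)
  no_tie <- !got$tie_broken
  expect_identical(got$voted[no_tie], sw$voted[no_tie])
  expect_error(majority_vote("HVHA", "HVHA", "XX"), "outside")
  # alternative tie rules
  expect_equal(majority_vote("HVHA", "LVLA", "LVHA", tie_rule = "svm")$voted,
               "HVHA")
})

test_that("the bundle trains all members on one set and votes", {
  sf <- separable_features(n_per_class = 15, seed = 6)
  b <- train_classifier_bundle(sf$features, sf$labels,
                               opts = list(svm_cost = 1, rf_trees = 50L,
                                           lstm_hidden = 8L,
                                           lstm_epochs = 25L,
                                           lstm_steps = 4L,
                                           tie_rule = "lstm"),
                               seed = 3)
  pv <- predict(b, sf$features)
  expect_named(pv, c("svm", "rf", "lstm", "voted", "votes", "tie_broken"))
  expect_gte(mean(pv$voted == sf$labels), 0.95)
})
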