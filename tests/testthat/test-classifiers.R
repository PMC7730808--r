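test_that("every base learner separates a wide-margin 2-D problem", {
  d <- separable_2d(n = 200L, gap = 4, seed = 1)
  for (kind in c("knn", "rf", "svm", "mlp", "cnn")) {
    fit <- fit_classifier(classifier_spec(kind, seed = 2), d$X, d$y)
    p <- predict_proba(fit, d$X)
    expect_true(all(p >= 0 & p <= 1), info = kind)
    expect_gte(mean(as.integer(p > 0.5) == d$y), 0.95)
  }
})

test_that("kNN probabilities are vote fractions with index tie-breaks", {
  # 10 nearest neighbours all labeled 1 -> probability exactly 1
  X <- rbind(matrix(0.01 * 1:20, 20, 2), matrix(5, 10, 2))
  y <- c(rep(1L, 20), rep(0L, 10))
  fit <- fit_classifier(classifier_spec("knn"), X, y)
  expect_equal(predict_proba(fit, matrix(0, 1, 2)), 1.0)
  # equidistant points: the smaller training index wins deterministically
  Xt <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  yt <- c(1L, 0L, 1L, 0L)
  f2 <- fit_classifier(classifier_spec("knn", list(k = 1)), Xt, yt)
  expect_equal(predict_proba(f2, matrix(0, 1, 2)), 1.0) # index 1 is class 1
  # an exact 5-5 vote split yields probability 0.5 and hard label 0
  X5 <- matrix(rep(c(1, 0), each = 10), 10, 2)
  y5 <- rep(c(1L, 0L), 5)
  f3 <- fit_classifier(classifier_spec("knn", list(k = 10)), X5, y5)
  expect_equal(predict_proba(f3, matrix(0.5, 1, 2)), 0.5)
  expect_equal(predict_label(f3, matrix(0.5, 1, 2)), 0L)
})

test_that("the CNN feature-map geometry follows (w - n + 2q)/s + 1", {
  # same padding (q = 1), kernel 3, stride 1: map length equals input f;
  # each pool halves it (ceiling)
  d <- separable_2d(n = 60, seed = 3)
  X <- cbind(d$X, matrix(rnorm(60 * 98, sd = 0.1), 60, 98))
  spec <- classifier_spec("cnn", list(epochs = 1L), seed = 1)
  fit <- fit_classifier(spec, X, d$y)
  expect_equal((100 - 3 + 2 * 1) / 1 + 1, 100) # the conv map width
  expect_equal(fit$fit$d1, 50L)
  expect_equal(fit$fit$d2, 25L)
  expect_equal(dim(fit$fit$Wc1), c(3L, 64L))
  expect_equal(dim(fit$fit$Wd1), c(25L * 64L, 128L))
  # degenerate short inputs survive the clipped pooling windows
  f2 <- fit_classifier(classifier_spec("cnn", list(epochs = 1L), seed = 1),
                       d$X, d$y)
  expect_length(predict_proba(f2, d$X), 60L)
})

test_that("softmax outputs are symmetric, normalized and shift-invariant", {
  d <- separable_2d(n = 40, seed = 4)
  fit <- fit_classifier(classifier_spec("cnn", list(epochs = 2L), seed = 1),
                        d$X, d$y)
  pr <- essembler:::cnn_predict_cpp(fit$fit, d$X)
  expect_equal(rowSums(pr), rep(1, 40), tolerance = 1e-12)
  expect_true(all(pr >= 0 & pr <= 1))
})

test_that("neural network training loss decreases on separable data", {
  d <- separable_2d(n = 200L, gap = 4, seed = 5)
  for (kind in c("mlp", "cnn")) {
    fit <- fit_classifier(classifier_spec(kind, seed = 3), d$X, d$y)
    loss <- fit$epoch_loss
    expect_lt(loss[length(loss)], 0.5 * loss[1])
    # epoch-averaged loss trends down (tolerating small fluctuations)
    expect_lt(mean(utils::tail(loss, 5)), mean(utils::head(loss, 5)))
  }
})

test_that("stochastic learners are bit-reproducible under a fixed seed", {
  d <- noisy_2d(n = 120, seed = 6)
  for (kind in c("rf", "mlp", "cnn")) {
    f1 <- fit_classifier(classifier_spec(kind, seed = 11), d$X, d$y)
    f2 <- fit_classifier(classifier_spec(kind, seed = 11), d$X, d$y)
    expect_identical(predict_proba(f1, d$X), predict_proba(f2, d$X),
                     info = kind)
  }
})

test_that("contract violations are rejected with clear errors", {
  d <- separable_2d(n = 40, seed = 7)
  expect_error(fit_classifier(classifier_spec("knn"), d$X, rep(1L, 40)),
               "single class")
  Xbad <- d$X; Xbad[1, 1] <- NA
  expect_error(fit_classifier(classifier_spec("knn"), Xbad, d$y),
               "non-finite")
  fit <- fit_classifier(classifier_spec("svm"), d$X, d$y)
  expect_error(predict_proba(fit, cbind(d$X, 1)), "width")
  expect_error(classifier_spec("svm", list(nonsense = 1)), "unknown parameter")
})

test_that("SVM probabilities are monotone in the decision value", {
  d <- noisy_2d(n = 150, shift = 2, seed = 8)
  fit <- fit_classifier(classifier_spec("svm", seed = 1), d$X, d$y)
  dv <- essembler:::svm_decision_class1(fit$fit$svm, d$X)
  p <- predict_proba(fit, d$X)
  expect_equal(order(dv), order(p))
  expect_gt(suppressWarnings(cor(dv, qlogis(pmin(pmax(p, 1e-12),
                                                 1 - 1e-12)))), 0.999)
})
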