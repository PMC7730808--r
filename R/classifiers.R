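#' Base classifier specification
#'
#' Uniform wrapper around the five base learners with their tuned
#' defaults: kNN (k = 10, Euclidean distance), random forest (500 trees,
#' 20 candidate features per split, Gini impurity), RBF-kernel SVM
#' (C = 32768 = 2^15, gamma = 0.001953125 = 2^-9, Platt-scaled
#' probabilities), MLP (hidden layers 100-50, ReLU, sigmoid output,
#' 50% dropout, Adam, lr 0.001, 100 epochs) and a 1-D CNN (64 filters,
#' kernel 3, two conv/max-pool blocks, dense 128-64, softmax output,
#' 10% dropout, Adadelta).
#'
#' @param kind One of `"knn"`, `"rf"`, `"svm"`, `"mlp"`, `"cnn"`.
#' @param params Named list of kind-specific overrides (see Details).
#' @param seed Integer seed for the stochastic learners.
#' @details Overridable parameters: `knn`: `k`. `rf`: `ntree`, `mtry`
#'   (number, or `"sqrt"` for the square root of the feature count).
#'   `svm`: `cost`, `gamma`. `mlp`: `hidden`, `dropout`, `lr`, `epochs`,
#'   `batch`. `cnn`: `n_filters`, `dropout`, `epochs`, `batch`, `dense`,
#'   `rho`, `eps`.
#' @return A `classifier_spec` object.
#' @export
classifier_spec <- function(kind = c("knn", "rf", "svm", "mlp", "cnn"),
                            params = list(), seed = 1L) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    knn = list(k = 10L),
    rf  = list(ntree = 500L, mtry = 20),
    svm = list(cost = 32768, gamma = 0.001953125),
    mlp = list(hidden = c(100L, 50L), dropout = 0.5, lr = 0.001,
               epochs = 100L, batch = 32L),
    cnn = list(n_filters = 64L, dropout = 0.1, epochs = 30L, batch = 32L,
               dense = c(128L, 64L), rho = 0.95, eps = 1e-6))
  override <- params
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown) > 0L)
    stop("unknown parameter(s) for ", kind, ": ",
         paste(unknown, collapse = ", "))
  params <- utils::modifyList(defaults, override)
  validate_spec_params(kind, params)
  structure(list(kind = kind, params = params, seed = as.integer(seed)),
            class = "classifier_spec")
}

validate_spec_params <- function(kind, p) {
  ok <- switch(kind,
    knn = p$k >= 1,
    rf  = p$ntree >= 1 && (identical(p$mtry, "sqrt") || p$mtry >= 1),
    svm = p$cost > 0 && p$gamma > 0,
    mlp = all(p$hidden >= 1) && p$dropout >= 0 && p$dropout < 1 &&
          p$lr > 0 && p$epochs >= 1 && p$batch >= 1,
    cnn = p$n_filters >= 1 && p$dropout >= 0 && p$dropout < 1 &&
          p$epochs >= 1 && p$batch >= 1 && all(p$dense >= 1))
  if (!isTRUE(ok)) stop("invalid parameters for classifier kind '", kind, "'")
  invisible(TRUE)
}

check_xy <- function(X, y) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("X and y are not aligned")
  if (!all(is.finite(X))) stop("non-finite values in feature matrix")
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("labels must be 0/1")
  if (length(unique(y)) < 2L)
    stop("training data contains a single class; both classes required")
  list(X = X, y = y)
}

#' Fit a base classifier
#'
#' @param spec A [classifier_spec()].
#' @param X Numeric feature matrix (samples x features).
#' @param y 0/1 label vector aligned with `X`.
#' @return A `fitted_model` with elements `spec`, `fit` and (for MLP/CNN)
#'   `epoch_loss`.
#' @export
fit_classifier <- function(spec, X, y) {
  stopifnot(inherits(spec, "classifier_spec"))
  d <- check_xy(X, y)
  X <- d$X; y <- d$y
  p <- spec$params
  fit <- switch(spec$kind,
    knn = list(X = X, y = y, k = as.integer(p$k)),
    rf = {
      set.seed(spec$seed)
      mtry <- if (identical(p$mtry, "sqrt")) max(1L, floor(sqrt(ncol(X))))
              else min(as.integer(p$mtry), ncol(X))
      randomForest::randomForest(x = X, y = factor(y, levels = c(0, 1)),
                                 ntree = as.integer(p$ntree), mtry = mtry)
    },
    svm = {
      set.seed(spec$seed)
      m <- e1071::svm(x = X, y = factor(y, levels = c(0, 1)),
                      kernel = "radial", cost = p$cost, gamma = p$gamma,
                      scale = FALSE)
      dv <- svm_decision_class1(m, X)
      list(svm = m, platt = platt_fit(dv, y))
    },
    mlp = mlp_train(X, y, hidden = p$hidden, dropout = p$dropout,
                    lr = p$lr, epochs = p$epochs, batch = p$batch,
                    seed = spec$seed),
    cnn = cnn_train_cpp(X, y, as.integer(p$n_filters),
                        as.integer(p$epochs), as.integer(p$batch),
                        p$dropout, p$rho, p$eps, as.integer(p$dense[1]),
                        as.integer(p$dense[2]), as.double(spec$seed)))
  out <- structure(list(spec = spec, fit = fit, width = ncol(X)),
                   class = c(paste0("fitted_", spec$kind), "fitted_model"))
  if (spec$kind %in% c("mlp", "cnn"))
    out$epoch_loss <- as.numeric(fit$epoch_loss)
  out
}

#' Class-1 probability predictions from a fitted model
#'
#' kNN returns the neighbour vote fraction (ties in distance broken by
#' the smaller training index); RF the tree-vote fraction; SVM
#' Platt-scaled decision values; MLP the sigmoid output; CNN the softmax
#' class-1 output.
#'
#' @param model A `fitted_model` (or `ensemble_model`).
#' @param X Feature matrix with the training width.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_proba <- function(model, X) UseMethod("predict_proba")

check_width <- function(model, X) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (ncol(X) != model$width)
    stop("feature width ", ncol(X), " does not match training width ",
         model$width)
  X
}

#' @export
predict_proba.fitted_knn <- function(model, X) {
  X <- check_width(model, X)
  tr <- model$fit$X
  k <- min(model$fit$k, nrow(tr))
  # squared Euclidean distances, test x train
  d2 <- outer(rowSums(X^2), rowSums(tr^2), "+") - 2 * X %*% t(tr)
  apply(d2, 1L, function(row) {
    nn <- order(row)[seq_len(k)]        # stable: distance ties -> smaller index
    mean(model$fit$y[nn])
  })
}

#' @export
predict_proba.fitted_rf <- function(model, X) {
  X <- check_width(model, X)
  unname(stats::predict(model$fit, X, type = "prob")[, "1"])
}

svm_decision_class1 <- function(m, X) {
  dv <- attr(stats::predict(m, X, decision.values = TRUE),
             "decision.values")
  # libsvm orients decision values toward the class named first in the
  # "A/B" column label; flip so larger values favour class 1
  if (startsWith(colnames(dv)[1], "1/")) dv[, 1] else -dv[, 1]
}

# Platt (1999) sigmoid fit p = 1/(1+exp(A*f+B)) by the robust Newton
# iteration of Lin, Weng & Keerthi (2007); deterministic.
platt_fit <- function(f, y, max_iter = 100L) {
  prior1 <- sum(y == 1); prior0 <- sum(y == 0)
  hi <- (prior1 + 1) / (prior1 + 2); lo <- 1 / (prior0 + 2)
  t <- ifelse(y == 1, hi, lo)
  A <- 0; B <- log((prior0 + 1) / (prior1 + 1))
  eps <- 1e-10; sigma <- 1e-12
  fApB <- A * f + B
  fval <- sum(ifelse(fApB >= 0, t * fApB + log1p(exp(-fApB)),
                     (t - 1) * fApB + log1p(exp(fApB))))
  for (it in seq_len(max_iter)) {
    fApB <- A * f + B
    p <- ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)),
                1 / (1 + exp(fApB)))
    q <- 1 - p
    d1 <- t - p
    d2 <- p * q
    g1 <- sum(f * d1); g2 <- sum(d1)
    if (abs(g1) < 1e-5 && abs(g2) < 1e-5) break
    h11 <- sum(f * f * d2) + sigma
    h22 <- sum(d2) + sigma
    h21 <- sum(f * d2)
    det <- h11 * h22 - h21 * h21
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    gd <- g1 * dA + g2 * dB
    step <- 1
    while (step >= 1e-10) {
      nA <- A + step * dA; nB <- B + step * dB
      fApB <- nA * f + nB
      newf <- sum(ifelse(fApB >= 0, t * fApB + log1p(exp(-fApB)),
                         (t - 1) * fApB + log1p(exp(fApB))))
      if (newf < fval + 1e-4 * step * gd) {
        A <- nA; B <- nB; fval <- newf
        break
      }
      step <- step / 2
    }
    if (step < 1e-10) break
  }
  c(A = A, B = B)
}

platt_predict <- function(ab, f) {
  fApB <- ab["A"] * f + ab["B"]
  unname(ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)),
                1 / (1 + exp(fApB))))
}

#' @export
predict_proba.fitted_svm <- function(model, X) {
  X <- check_width(model, X)
  platt_predict(model$fit$platt, svm_decision_class1(model$fit$svm, X))
}

#' @export
predict_proba.fitted_mlp <- function(model, X) {
  X <- check_width(model, X)
  mlp_forward(model$fit, X)
}

#' @export
predict_proba.fitted_cnn <- function(model, X) {
  X <- check_width(model, X)
  cnn_predict_cpp(model$fit, X)[, 2]
}

#' Hard labels from a fitted base classifier
#'
#' Base classifiers label with `proba > 0.5`, so an exact vote tie (e.g.
#' a 5-5 kNN split) resolves to class 0.
#'
#' @param model A `fitted_model`.
#' @param X Feature matrix.
#' @return Integer 0/1 vector.
#' @export
predict_label <- function(model, X) as.integer(predict_proba(model, X) > 0.5)

#' @export
print.fitted_model <- function(x, ...) {
  cat("fitted_model:", x$spec$kind, "( width", x$width, ")\n")
  invisible(x)
}
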