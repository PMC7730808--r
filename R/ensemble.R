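#' Stacking ensemble specification
#'
#' Stacked generalization: base members produce out-of-fold class-1
#' probabilities which feed an ordinary-least-squares linear meta-learner
#' with intercept; members are then refit on the full training data. The
#' validated default membership is MLP + CNN + SVM; the full five-member
#' set (kNN, RF, SVM, MLP, CNN) is available by listing it.
#'
#' @param members Character vector of classifier kinds, or a list of
#'   [classifier_spec()] objects.
#' @param oof_folds Internal stratified fold count used to generate
#'   out-of-fold meta-features.
#' @param threshold Decision threshold on the meta score (a score equal
#'   to the threshold labels 1).
#' @param seed Integer seed (propagated to members and internal folds).
#' @return An `ensemble_spec` object.
#' @export
ensemble_spec <- function(members = c("mlp", "cnn", "svm"), oof_folds = 5L,
                          threshold = 0.5, seed = 1L) {
  if (is.character(members))
    members <- lapply(members, function(k) classifier_spec(k, seed = seed))
  stopifnot(length(members) >= 1L,
            all(vapply(members, inherits, logical(1), "classifier_spec")),
            threshold > 0, threshold < 1, oof_folds >= 2L)
  structure(list(members = members, meta = "linear",
                 oof_folds = as.integer(oof_folds),
                 threshold = threshold, seed = as.integer(seed)),
            class = "ensemble_spec")
}

#' Out-of-fold meta-feature matrix
#'
#' Column j, row i holds the class-1 probability for sample i from
#' member j trained with sample i's internal fold held out, so the
#' meta-learner never sees resubstitution outputs. Internal folds are
#' stratified so every internal training set contains both classes.
#'
#' @param spec An [ensemble_spec()].
#' @param X Feature matrix.
#' @param y Aligned 0/1 labels.
#' @return n x m matrix of probabilities.
#' @export
make_meta_features <- function(spec, X, y) {
  d <- check_xy(X, y)
  X <- d$X; y <- d$y
  set.seed(spec$seed)
  folds <- integer(length(y))
  for (cl in c(0L, 1L))
    folds[y == cl] <- balanced_folds(sum(y == cl), spec$oof_folds)
  meta <- matrix(NA_real_, nrow(X), length(spec$members))
  colnames(meta) <- vapply(spec$members, function(m) m$kind, character(1))
  for (fd in seq_len(spec$oof_folds)) {
    hold <- which(folds == fd)
    keep <- which(folds != fd)
    for (j in seq_along(spec$members)) {
      mspec <- spec$members[[j]]
      mspec$seed <- spec$seed + 100L * fd + j
      fit <- fit_classifier(mspec, X[keep, , drop = FALSE], y[keep])
      meta[hold, j] <- predict_proba(fit, X[hold, , drop = FALSE])
    }
  }
  meta
}

# OLS of y on meta columns with intercept; ridge fallback on singular
# design (alpha = 1e-6) with a warning
fit_meta <- function(meta, y, alpha = 1e-6) {
  Z <- cbind(intercept = 1, meta)
  qrz <- qr(Z)
  if (qrz$rank < ncol(Z)) {
    warning("singular meta-feature design; using ridge fallback ",
            "(alpha = ", alpha, ")")
    beta <- solve(crossprod(Z) + diag(alpha, ncol(Z)), crossprod(Z, y))
    as.numeric(beta)
  } else {
    as.numeric(qr.coef(qrz, y))
  }
}

#' Fit a stacking ensemble
#'
#' Generates out-of-fold meta-features, fits the linear meta-learner by
#' ordinary least squares (ridge fallback when members are collinear),
#' then refits every member on the full training data.
#'
#' @param spec An [ensemble_spec()].
#' @param X Feature matrix.
#' @param y Aligned 0/1 labels.
#' @return An `ensemble_model`: fitted `members`, meta `beta`
#'   (intercept first), `threshold`, `width`.
#' @export
fit_ensemble <- function(spec, X, y) {
  d <- check_xy(X, y)
  X <- d$X; y <- d$y
  meta <- make_meta_features(spec, X, y)
  beta <- fit_meta(meta, y)
  members <- lapply(seq_along(spec$members), function(j) {
    mspec <- spec$members[[j]]
    mspec$seed <- spec$seed + j
    fit_classifier(mspec, X, y)
  })
  structure(list(spec = spec, members = members, beta = beta,
                 threshold = spec$threshold, width = ncol(X)),
            class = "ensemble_model")
}

member_probas <- function(model, X) {
  vapply(model$members, function(m) predict_proba(m, X),
         numeric(nrow(X)))
}

#' @export
predict_proba.ensemble_model <- function(model, X) {
  if (!is.matrix(X)) X <- as.matrix(X)
  X <- check_width(model, X)
  P <- member_probas(model, X)
  if (!is.matrix(P)) P <- matrix(P, nrow = nrow(X))
  raw <- model$beta[1] + P %*% model$beta[-1]
  pmin(pmax(as.numeric(raw), 0), 1)
}

#' Predict with a fitted stacking ensemble
#'
#' @param object An `ensemble_model`.
#' @param newdata Feature matrix with the training width.
#' @param ... Unused.
#' @return A data frame with `score` (clipped meta score in `[0, 1]`)
#'   and `label` (1 when `score >= threshold`).
#' @export
predict.ensemble_model <- function(object, newdata, ...) {
  score <- predict_proba(object, newdata)
  data.frame(score = score,
             label = as.integer(score >= object$threshold))
}

#' @export
print.ensemble_model <- function(x, ...) {
  kinds <- vapply(x$members, function(m) m$spec$kind, character(1))
  cat("ensemble_model:", paste(kinds, collapse = " + "),
      "| beta =", paste(signif(x$beta, 4), collapse = ", "),
      "| threshold =", x$threshold, "\n")
  invisible(x)
}
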