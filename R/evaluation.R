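#' Confusion counts for binary predictions
#'
#' @param y_true 0/1 vector of reference labels.
#' @param y_pred Aligned 0/1 vector of predicted labels.
#' @return A `confusion_counts` object: `TP`, `TN`, `FP`, `FN`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred have different lengths")
  if (length(y_true) == 0L) stop("empty input")
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  stopifnot(all(y_true %in% c(0L, 1L)), all(y_pred %in% c(0L, 1L)))
  structure(list(TP = sum(y_true == 1L & y_pred == 1L),
                 TN = sum(y_true == 0L & y_pred == 0L),
                 FP = sum(y_true == 0L & y_pred == 1L),
                 FN = sum(y_true == 1L & y_pred == 0L)),
            class = "confusion_counts")
}

#' Area under the ROC curve by the rank (Mann-Whitney) formulation
#'
#' Equals the probability that a random positive outscores a random
#' negative, with score ties counted one half (mean ranks), and is
#' therefore threshold-free.
#'
#' @param scores Numeric scores, larger = more positive.
#' @param labels Aligned 0/1 labels.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("AUC requires both classes in the evaluated set")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics from confusion counts
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP) and accuracy =
#' (TP+TN)/n, reported as percentages; the Matthews correlation
#' coefficient
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}}
#' with the 0-by-convention value when any denominator factor is zero;
#' and, when `scores` are supplied, the rank-based AUC.
#'
#' @param cc A `confusion_counts` object.
#' @param scores Optional numeric scores for AUC.
#' @param labels Optional 0/1 labels aligned with `scores` (required
#'   when `scores` given).
#' @return A named list: `sens`, `spec`, `acc` (percent), `mcc`, `auc`
#'   (`NA` without scores).
#' @export
classification_metrics <- function(cc, scores = NULL, labels = NULL) {
  stopifnot(inherits(cc, "confusion_counts"))
  n <- cc$TP + cc$TN + cc$FP + cc$FN
  if (n == 0L) stop("empty confusion table")
  sens <- if (cc$TP + cc$FN == 0L) NA_real_ else 100 * cc$TP / (cc$TP + cc$FN)
  spec <- if (cc$TN + cc$FP == 0L) NA_real_ else 100 * cc$TN / (cc$TN + cc$FP)
  acc <- 100 * (cc$TP + cc$TN) / n
  tp <- as.numeric(cc$TP); tn <- as.numeric(cc$TN)
  fp <- as.numeric(cc$FP); fn <- as.numeric(cc$FN)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / sqrt(denom)
  auc <- if (is.null(scores)) NA_real_ else auc_rank(scores, labels)
  list(sens = sens, spec = spec, acc = acc, mcc = mcc, auc = auc)
}

#' Cross-validation plan
#'
#' Random allocation of `n` samples to `k` near-equal folds, repeated
#' `repeats` times. Within every repeat the folds are disjoint, cover
#' all indices and differ in size by at most one. Stratified allocation
#' (balancing class frequencies per fold) is off by default.
#'
#' @param n Number of samples.
#' @param k Number of folds.
#' @param repeats Number of independent repetitions.
#' @param stratified Balance labels across folds (requires `labels`
#'   at assignment time).
#' @param seed Integer seed.
#' @return A `cv_plan` object; `assignment(plan, labels)` materializes
#'   fold ids.
#' @export
cv_plan <- function(n, k = 5L, repeats = 10L, stratified = FALSE,
                    seed = 1L) {
  n <- as.integer(n); k <- as.integer(k); repeats <- as.integer(repeats)
  stopifnot(n >= k, k >= 2L, repeats >= 1L)
  structure(list(n = n, k = k, repeats = repeats, stratified = stratified,
                 seed = as.integer(seed)),
            class = "cv_plan")
}

# balanced random fold ids for m samples
balanced_folds <- function(m, k) {
  sizes <- rep(m %/% k, k) + c(rep(1L, m %% k), rep(0L, k - m %% k))
  sample(rep.int(seq_len(k), sizes))
}

#' Materialize fold assignments of a plan
#'
#' @param plan A [cv_plan()].
#' @param labels 0/1 labels, needed when `plan$stratified`.
#' @return List of integer vectors (one per repeat) with fold ids in
#'   `1..k` for each sample.
#' @export
fold_assignments <- function(plan, labels = NULL) {
  lapply(seq_len(plan$repeats), function(r) {
    set.seed(plan$seed + r)
    if (!plan$stratified) {
      balanced_folds(plan$n, plan$k)
    } else {
      if (is.null(labels) || length(labels) != plan$n)
        stop("stratified assignment requires labels of length n")
      f <- integer(plan$n)
      for (cl in unique(labels))
        f[labels == cl] <- balanced_folds(sum(labels == cl), plan$k)
      f
    }
  })
}

resolve_features <- function(dataset, features) {
  if (inherits(features, "embedding_params")) {
    featurize_dataset(dataset, features)
  } else if (is.function(features)) {
    featurize_baseline(dataset, features)
  } else if (is.list(features) && all(c("X", "y") %in% names(features))) {
    features
  } else stop("features must be embedding_params, a featurizer function, ",
              "or a precomputed list(X, y)")
}

#' Repeated k-fold cross-validation of a classification pipeline
#'
#' Featurizes the dataset once (embedding training is unsupervised, so
#' it sees no labels), then for every repeat and fold: optionally
#' oversamples the training rows only, fits the model, and scores the
#' held-out rows. Per-fold metrics are averaged (mean and sd across all
#' repeat-fold cells); a pooled-prediction AUC per repeat is also
#' reported. Fully deterministic for a fixed plan seed.
#'
#' @param dataset A `gene_dataset`.
#' @param features An [embedding_params()], a featurizer function (one
#'   sequence string to a numeric vector), or a precomputed
#'   `list(X, y)`.
#' @param model An [ensemble_spec()] or a [classifier_spec()].
#' @param plan A [cv_plan()] with `n = length(dataset)`.
#' @param smote Optional [smote_config()]; applied inside training folds
#'   only.
#' @return A `cv_report`: `per_fold` data frame, `summary` (mean/sd per
#'   metric), `pooled_auc`, `member_auc` summary (ensembles), and a
#'   `manifest` recording seeds, configuration and fold assignments.
#' @export
run_cv <- function(dataset, features = embedding_params(),
                   model = ensemble_spec(), plan = NULL, smote = NULL) {
  feat <- resolve_features(dataset, features)
  X <- feat$X; y <- feat$y
  if (length(unique(y)) < 2L) stop("dataset must contain both classes")
  if (is.null(plan)) plan <- cv_plan(nrow(X), k = 5L, repeats = 10L)
  if (plan$n != nrow(X)) stop("plan$n does not match dataset size")
  assigns <- fold_assignments(plan, y)
  is_ens <- inherits(model, "ensemble_spec")
  member_names <- if (is_ens) vapply(model$members, function(m) m$kind,
                                     character(1))
  rows <- list()
  audit <- list()
  pooled <- numeric(plan$repeats)
  for (r in seq_len(plan$repeats)) {
    folds <- assigns[[r]]
    rep_scores <- numeric(plan$n)
    for (fd in seq_len(plan$k)) {
      test <- which(folds == fd)
      train <- which(folds != fd)
      if (length(unique(y[train])) < 2L || length(unique(y[test])) < 2L)
        stop("fold ", fd, " of repeat ", r, " has a single class; ",
             "consider stratified = TRUE")
      fold_seed <- plan$seed + 1000L * r + fd
      Xtr <- X[train, , drop = FALSE]; ytr <- y[train]
      if (!is.null(smote)) {
        cfg <- smote; cfg$seed <- fold_seed
        aug <- oversample(Xtr, ytr, cfg)
        Xtr <- aug$X; ytr <- aug$y
        # leakage audit trail: exact row keys of every augmented training
        # row and of the held-out rows for this cell
        audit[[length(audit) + 1L]] <- list(
          repeat_ = r, fold = fd,
          train_keys = row_keys(Xtr),
          test_keys = row_keys(X[test, , drop = FALSE]))
      }
      if (is_ens) {
        spec <- model; spec$seed <- fold_seed
        fit <- fit_ensemble(spec, Xtr, ytr)
        pr <- stats::predict(fit, X[test, , drop = FALSE])
        scores <- pr$score; labels_hat <- pr$label
        mauc <- vapply(seq_along(fit$members), function(j) {
          auc_rank(predict_proba(fit$members[[j]], X[test, , drop = FALSE]),
                   y[test])
        }, numeric(1))
      } else {
        spec <- model; spec$seed <- fold_seed
        fit <- fit_classifier(spec, Xtr, ytr)
        scores <- predict_proba(fit, X[test, , drop = FALSE])
        labels_hat <- as.integer(scores > 0.5)
        mauc <- NULL
      }
      rep_scores[test] <- scores
      cc <- confusion(y[test], labels_hat)
      m <- classification_metrics(cc, scores, y[test])
      row <- data.frame(repeat_ = r, fold = fd, TP = cc$TP, TN = cc$TN,
                        FP = cc$FP, FN = cc$FN, sens = m$sens,
                        spec = m$spec, acc = m$acc, mcc = m$mcc,
                        auc = m$auc)
      if (is_ens)
        row[paste0("auc_", member_names)] <- as.list(mauc)
      rows[[length(rows) + 1L]] <- row
    }
    pooled[r] <- auc_rank(rep_scores, y)
  }
  per_fold <- do.call(rbind, rows)
  metric_cols <- setdiff(names(per_fold), c("repeat_", "fold"))
  summ <- data.frame(metric = metric_cols,
                     mean = vapply(per_fold[metric_cols], mean, numeric(1)),
                     sd = vapply(per_fold[metric_cols], stats::sd,
                                 numeric(1)),
                     row.names = NULL)
  manifest <- list(
    n = plan$n, k = plan$k, repeats = plan$repeats,
    stratified = plan$stratified, seed = plan$seed,
    smote = if (is.null(smote)) NULL else unclass(smote),
    model = summarize_model_spec(model),
    features = summarize_features(features),
    fold_assignments = assigns,
    fold_md5 = vapply(assigns, hash_object, character(1)),
    smote_audit = audit)
  structure(list(per_fold = per_fold, summary = summ,
                 pooled_auc = pooled, manifest = manifest),
            class = "cv_report")
}

summarize_model_spec <- function(model) {
  if (inherits(model, "ensemble_spec")) {
    list(type = "ensemble",
         members = lapply(model$members, function(m)
           list(kind = m$kind, params = m$params)),
         meta = model$meta, oof_folds = model$oof_folds,
         threshold = model$threshold, seed = model$seed)
  } else {
    list(type = "single", kind = model$kind, params = model$params,
         seed = model$seed)
  }
}

summarize_features <- function(features) {
  if (inherits(features, "embedding_params")) unclass(features)
  else if (is.function(features)) "custom featurizer function"
  else "precomputed matrix"
}

# injective full-precision text key per matrix row, for set comparisons
row_keys <- function(M)
  apply(M, 1L, function(r) paste(sprintf("%.17g", r), collapse = ","))

# md5 of the serialized object via a temp file (base tools only)
hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

#' @export
print.cv_report <- function(x, ...) {
  cat("cv_report:", x$manifest$repeats, "x", x$manifest$k,
      "-fold CV on n =", x$manifest$n, "\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-10s %8.3f +/- %.3f\n", s$metric[i], s$mean[i],
                s$sd[i]))
  cat(sprintf("  pooled AUC %8.3f\n", mean(x$pooled_auc)))
  invisible(x)
}

#' Write a CV report to disk (TSV per-fold table + JSON summary/manifest)
#'
#' @param report A `cv_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$per_fold, file.path(dir, "per_fold.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(summary = report$summary, pooled_auc = report$pooled_auc,
         manifest = report$manifest[setdiff(names(report$manifest),
                                            c("fold_assignments",
                                              "smote_audit"))]),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
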