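#' SMOTE configuration
#'
#' @param variant `"svm"` (default): synthesis seeded at the minority-class
#'   support vectors of an RBF-SVM fitted to the data, interpolating
#'   toward minority neighbours where the neighbourhood is majority-heavy
#'   and extrapolating (step bounded by half the neighbour distance)
#'   where it is minority-dense. `"regular"`: classic interpolation
#'   `x_new = x_i + u (x_nn - x_i)`, `u ~ U(0, 1)`, between random
#'   minority points and their minority nearest neighbours.
#' @param k_neighbors Number of minority nearest neighbours considered.
#' @param target Desired minority:majority ratio after resampling.
#' @param seed Integer seed.
#' @return A `smote_config` object.
#' @export
smote_config <- function(variant = c("svm", "regular"), k_neighbors = 5L,
                         target = 1.0, seed = 1L) {
  variant <- match.arg(variant)
  k_neighbors <- as.integer(k_neighbors)
  stopifnot(k_neighbors >= 1L, target > 0, target <= 1)
  structure(list(variant = variant, k_neighbors = k_neighbors,
                 target = target, seed = as.integer(seed)),
            class = "smote_config")
}

# index matrix of the k nearest rows of `among` for each row of `from`
# (self excluded when from and among share rows via `exclude_self` ids)
knn_index <- function(from, among, k, exclude = NULL) {
  d2 <- outer(rowSums(from^2), rowSums(among^2), "+") - 2 * from %*% t(among)
  t(vapply(seq_len(nrow(from)), function(i) {
    row <- d2[i, ]
    if (!is.null(exclude)) row[exclude[i]] <- Inf
    order(row)[seq_len(k)]
  }, integer(k)))
}

#' Oversample the minority class with SMOTE
#'
#' Synthesizes minority-class rows until the minority:majority ratio
#' reaches `cfg$target`. Original rows are preserved, in order, first;
#' only minority-labeled synthetic rows are appended. Already-balanced
#' input is returned unchanged. Must only ever be applied to training
#' rows; the cross-validation driver enforces this.
#'
#' @param X Numeric feature matrix.
#' @param y Aligned 0/1 labels.
#' @param cfg A [smote_config()].
#' @return List with augmented `X`, `y` and `n_synthetic`.
#' @export
oversample <- function(X, y, cfg = smote_config()) {
  if (!is.matrix(X)) X <- as.matrix(X)
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0L, 1L)))
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  minority <- if (n1 <= n0) 1L else 0L
  n_min <- min(n1, n0); n_maj <- max(n1, n0)
  n_syn <- ceiling(cfg$target * n_maj) - n_min
  if (n_syn <= 0)
    return(list(X = X, y = y, n_synthetic = 0L,
                synthetic = rep(FALSE, nrow(X))))
  if (n_min <= cfg$k_neighbors)
    stop("minority class has ", n_min, " samples but k_neighbors = ",
         cfg$k_neighbors, "; use a smaller k_neighbors")
  set.seed(cfg$seed)
  min_idx <- which(y == minority)
  Xmin <- X[min_idx, , drop = FALSE]
  syn <- if (cfg$variant == "regular") {
    smote_regular(Xmin, n_syn, cfg$k_neighbors)
  } else {
    smote_svm(X, y, Xmin, minority, n_syn, cfg$k_neighbors)
  }
  dimnames(syn) <- NULL
  Xa <- rbind(X, syn)
  if (!is.null(rownames(X)))
    rownames(Xa) <- c(rownames(X), paste0("syn", seq_len(nrow(syn))))
  list(X = Xa, y = c(y, rep(minority, nrow(syn))),
       n_synthetic = nrow(syn),
       synthetic = c(rep(FALSE, nrow(X)), rep(TRUE, nrow(syn))))
}

smote_regular <- function(Xmin, n_syn, k) {
  nn <- knn_index(Xmin, Xmin, k, exclude = seq_len(nrow(Xmin)))
  base <- sample.int(nrow(Xmin), n_syn, replace = TRUE)
  pick <- sample.int(k, n_syn, replace = TRUE)
  u <- stats::runif(n_syn)
  t(vapply(seq_len(n_syn), function(s) {
    xi <- Xmin[base[s], ]
    xn <- Xmin[nn[base[s], pick[s]], ]
    xi + u[s] * (xn - xi)
  }, numeric(ncol(Xmin))))
}

smote_svm <- function(X, y, Xmin, minority, n_syn, k) {
  m <- e1071::svm(x = X, y = factor(y, levels = c(0, 1)), kernel = "radial",
                  scale = FALSE)
  sv_rows <- m$index[y[m$index] == minority]
  if (length(sv_rows) == 0L) sv_rows <- which(y == minority)
  seeds <- X[sv_rows, , drop = FALSE]
  # minority neighbours of each seed (seed itself excluded when present)
  self <- match(sv_rows, which(y == minority))
  nn_min <- knn_index(seeds, Xmin, k, exclude = self)
  # neighbourhood composition over the whole training set decides
  # interpolation (majority-heavy) vs bounded extrapolation (minority-dense)
  nn_all <- knn_index(seeds, X, k, exclude = sv_rows)
  maj_frac <- rowMeans(matrix(y[nn_all] != minority, nrow(nn_all)))
  base <- rep_len(seq_len(nrow(seeds)), n_syn)
  pick <- sample.int(k, n_syn, replace = TRUE)
  u <- stats::runif(n_syn)
  t(vapply(seq_len(n_syn), function(s) {
    xi <- seeds[base[s], ]
    xn <- Xmin[nn_min[base[s], pick[s]], ]
    if (maj_frac[base[s]] > 0.5) xi + u[s] * (xn - xi)
    else xi + 0.5 * u[s] * (xi - xn)
  }, numeric(ncol(X))))
}
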