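BASES <- c("A", "C", "G", "T")

# all k-tuples over ACGT in lexicographic order
all_ktuples <- function(k) {
  grid <- do.call(expand.grid,
                  c(rep(list(BASES), k), stringsAsFactors = FALSE))
  # expand.grid varies the first factor fastest; reverse for lexicographic
  sort(apply(grid, 1L, paste, collapse = ""))
}

#' Overlapping k-mer composition of a sequence
#'
#' Counts of overlapping k-tuples normalized to frequencies, in
#' lexicographic tuple order. Tuples containing `N` are dropped before
#' normalization, so entries always sum to 1.
#'
#' @param seq A `gene_sequence` or character scalar.
#' @param k Tuple size.
#' @return Named numeric vector of length `4^k` summing to 1.
#' @export
kmer_counts <- function(seq, k = 4L) {
  if (inherits(seq, "gene_sequence")) seq <- seq$seq
  k <- as.integer(k)
  if (nchar(seq) < k)
    stop("sequence shorter than k = ", k)
  tuples <- all_ktuples(k)
  toks <- tokenize(seq, k)
  if (length(toks) == 0L)
    stop("no unambiguous k-tuples in sequence")
  counts <- table(factor(toks, levels = tuples))
  out <- as.numeric(counts) / length(toks)
  names(out) <- tuples
  out
}

# SantaLucia (1998) unified nearest-neighbor thermodynamics for the 16
# dinucleotide steps: enthalpy dH (kcal/mol), entropy dS (cal/mol/K) and
# free energy dG37 (kcal/mol). Complementary steps share values.
santalucia_nn <- function() {
  base10 <- rbind(
    AA = c(-7.9, -22.2, -1.00), AT = c(-7.2, -20.4, -0.88),
    TA = c(-7.2, -21.3, -0.58), CA = c(-8.5, -22.7, -1.45),
    GT = c(-8.4, -22.4, -1.44), CT = c(-7.8, -21.0, -1.28),
    GA = c(-8.2, -22.2, -1.30), CG = c(-10.6, -27.2, -2.17),
    GC = c(-9.8, -24.4, -2.24), GG = c(-8.0, -19.9, -1.84))
  colnames(base10) <- c("dH", "dS", "dG37")
  rc <- function(x) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(x, "")[[1]]), collapse = ""))
  full <- matrix(NA_real_, 16L, 3L,
                 dimnames = list(all_ktuples(2L), colnames(base10)))
  for (tu in rownames(full)) {
    src <- if (tu %in% rownames(base10)) tu else rc(tu)
    full[tu, ] <- base10[src, ]
  }
  full
}

standardize_props <- function(props) {
  out <- apply(props, 2L, function(p) {
    s <- stats::sd(p)
    if (s == 0) rep(0, length(p)) else (p - mean(p)) / s
  })
  dimnames(out) <- dimnames(props)
  out
}

#' Default physicochemical property table for k-tuples
#'
#' Dinucleotide (`k = 2`): nearest-neighbor thermodynamic parameters
#' (enthalpy, entropy, free energy at 37C) of the 16 steps.
#' Trinucleotide (`k = 3`): the same parameters accumulated additively
#' over the two constituent steps of each triplet (the standard
#' nearest-neighbor additivity construction). Each property is
#' standardized to mean 0, sd 1 across tuples.
#'
#' @param k Tuple size, 2 or 3.
#' @return Matrix: rows = k-tuples (lexicographic), columns = properties.
#' @export
default_properties <- function(k = 2L) {
  di <- santalucia_nn()
  props <- if (k == 2L) {
    di
  } else if (k == 3L) {
    tri <- all_ktuples(3L)
    t(vapply(tri, function(tu) {
      di[substr(tu, 1, 2), ] + di[substr(tu, 2, 3), ]
    }, numeric(3L)))
  } else stop("default properties available for k = 2 or 3 only")
  standardize_props(props)
}

#' Read a user property table (TSV)
#'
#' Rows are k-tuples, columns named properties; values are standardized
#' to mean 0, sd 1 per property on load.
#'
#' @param path TSV path with a `tuple` first column.
#' @param k Tuple size the table must cover completely.
#' @return Standardized property matrix.
#' @export
read_property_table <- function(path, k) {
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE)
  tuples <- toupper(tab[[1]])
  need <- all_ktuples(k)
  if (!all(need %in% tuples))
    stop("property table is missing tuples: ",
         paste(utils::head(setdiff(need, tuples), 5L), collapse = ", "))
  m <- as.matrix(tab[match(need, tuples), -1, drop = FALSE])
  rownames(m) <- need
  storage.mode(m) <- "double"
  standardize_props(m)
}

#' PseKNC parameters
#'
#' @param k Tuple size (2 = dinucleotide, 3 = trinucleotide).
#' @param lam Number of correlation tiers lambda (0 reduces the feature
#'   to plain k-mer composition).
#' @param w Weight factor in (0, 1] balancing composition against
#'   correlation terms.
#' @param variant `"series"` (Type II: per-property correlation tiers,
#'   lambda counts total tiers in row-major tier-by-property order) or
#'   `"parallel"` (Type I: properties pooled in a single squared-difference
#'   correlation).
#' @param props Standardized property matrix (rows = k-tuples); defaults
#'   to [default_properties()].
#' @return A `pseknc_params` object.
#' @export
pseknc_params <- function(k = 2L, lam = 10L, w = 0.5,
                          variant = c("series", "parallel"), props = NULL) {
  variant <- match.arg(variant)
  k <- as.integer(k); lam <- as.integer(lam)
  stopifnot(k %in% c(2L, 3L), lam >= 0L, w > 0, w <= 1)
  if (is.null(props)) props <- default_properties(k)
  if (!all(all_ktuples(k) %in% rownames(props)))
    stop("property table must cover every k-tuple")
  structure(list(k = k, lam = lam, w = w, variant = variant,
                 props = props[all_ktuples(k), , drop = FALSE]),
            class = "pseknc_params")
}

#' Pseudo k-tuple nucleotide composition
#'
#' The PseKNC feature family: the first `4^k` entries are k-tuple
#' frequencies and the remaining `lambda` entries are tiered sequence-order
#' correlation factors weighted by `w`, normalized so the whole vector
#' sums to 1:
#' \deqn{d_u = f_u / (\sum f_i + w \sum \theta_j)}{d_u = f_u/(sum f + w sum theta)}
#' for the composition block and
#' \deqn{d_{4^k+j} = w\theta_j / (\sum f_i + w \sum \theta_j)}
#' for the correlation block. Parallel (Type I) correlation pools all P
#' properties, \eqn{\Theta = (1/P)\sum_q (P_q(T_i)-P_q(T_{i+j}))^2}; the
#' series (Type II) variant keeps one tier per (tier, property) pair using
#' the property product. `PseDNC` = k 2 series, `PCPseDNC` = k 2 parallel,
#' `PseTNC` = k 3 series, `PCPseTNC` = k 3 parallel.
#'
#' @param seq A `gene_sequence` or character scalar (no `N` in the
#'   correlation window; ambiguous tuples abort with an error).
#' @param p A [pseknc_params()] object.
#' @return Numeric vector of length `4^k + lam` summing to 1.
#' @export
pseknc <- function(seq, p = pseknc_params()) {
  if (inherits(seq, "gene_sequence")) seq <- seq$seq
  k <- p$k
  L <- nchar(seq)
  tuples_seq <- tokenize(seq, k)
  n_tuples <- L - k + 1L
  if (length(tuples_seq) != n_tuples)
    stop("pseknc requires an unambiguous sequence (no N)")
  P <- ncol(p$props)
  max_tier <- if (p$lam == 0L) 0L
              else if (p$variant == "parallel") p$lam
              else as.integer(ceiling(p$lam / P))
  if (max_tier >= L - k + 1L)
    stop("lambda too large for sequence length ", L,
         " (needs at least ", max_tier + k, " + 1 nt); reduce lam")
  f <- kmer_counts(seq, k)
  pv <- p$props[match(tuples_seq, rownames(p$props)), , drop = FALSE]
  theta <- numeric(p$lam)
  if (p$lam > 0L) {
    if (p$variant == "parallel") {
      for (j in seq_len(p$lam)) {
        i <- seq_len(n_tuples - j)
        d2 <- (pv[i, , drop = FALSE] - pv[i + j, , drop = FALSE])^2
        theta[j] <- mean(rowMeans(d2))
      }
    } else {
      for (m in seq_len(p$lam)) {
        j <- (m - 1L) %/% P + 1L
        q <- (m - 1L) %% P + 1L
        i <- seq_len(n_tuples - j)
        theta[m] <- mean(pv[i, q] * pv[i + j, q])
      }
    }
  }
  denom <- sum(f) + p$w * sum(theta)
  out <- c(f / denom, p$w * theta / denom)
  names(out) <- c(names(f), if (p$lam > 0L)
    paste0("theta", seq_len(p$lam)))
  out
}

#' Featurize a dataset with a baseline featurizer
#'
#' @param dataset A `gene_dataset`.
#' @param featurizer Function mapping one sequence string to a numeric
#'   vector, e.g. `function(s) kmer_counts(s, 4)` or
#'   `function(s) pseknc(s, pseknc_params(k = 2))`.
#' @return List with `X` (matrix, rownames = ids) and `y`.
#' @export
featurize_baseline <- function(dataset, featurizer) {
  seqs <- dataset_seqs(dataset)
  first <- featurizer(seqs[1])
  X <- t(vapply(seqs, featurizer, numeric(length(first))))
  rownames(X) <- dataset_ids(dataset)
  list(X = X, y = dataset_labels(dataset))
}
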