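# Fixtures are built in code at test time; nothing binary is stored.

write_tmp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# well-separated two-cluster 2-D data (margin >> noise)
separable_2d <- function(n = 200L, gap = 4, seed = 1L) {
  set.seed(seed)
  half <- n %/% 2L
  X <- rbind(matrix(stats::rnorm(2 * half, -gap / 2, 0.5), half, 2L),
             matrix(stats::rnorm(2 * half, gap / 2, 0.5), half, 2L))
  list(X = X, y = rep(c(0L, 1L), each = half))
}

# moderately overlapping gaussian classes (for probabilistic learners)
noisy_2d <- function(n = 200L, shift = 1.5, seed = 1L) {
  set.seed(seed)
  half <- n %/% 2L
  X <- rbind(matrix(stats::rnorm(2 * half, 0), half, 2L),
             matrix(stats::rnorm(2 * half, shift), half, 2L))
  list(X = X, y = rep(c(0L, 1L), each = half))
}

random_dna <- function(L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

small_motif_dataset <- function(n_pos = 40L, n_neg = 80L, plant_rate = 2,
                                seed = 5L, lengths = c(200L, 500L)) {
  generate_dataset(synth_config(n_pos = n_pos, n_neg = n_neg,
                                length_range = lengths,
                                plant_rate = plant_rate, seed = seed))
}

cheap_ensemble <- function(seed = 1L)
  ensemble_spec(c("knn", "svm"), seed = seed)
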