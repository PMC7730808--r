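DEFAULT_MOTIFS <- c("ACGTAG", "TTGACC", "GCATCG", "CAGTTA")

#' Synthetic dataset configuration
#'
#' Generates two classes of random nucleotide sequences shaped like a
#' bacterial/archaeal gene benchmark: lengths uniform in
#' `length_range`, i.i.d. background bases, and a compositional class
#' signal in the positives — hexamer motifs planted at a Poisson rate
#' per 100 nt and/or a GC-content shift. Motifs are planted by
#' overwriting (not insertion) so the length distribution is
#' label-independent and length is not a confound.
#'
#' @param n_pos,n_neg Class sizes.
#' @param length_range Integer range of sequence lengths (nt).
#' @param base_probs Background probabilities for A, C, G, T (sum 1).
#' @param motifs Character vector of planted motifs (default 4 fixed
#'   hexamers).
#' @param plant_rate Expected planted motifs per 100 nt in positives
#'   (0 = no motif signal).
#' @param gc_shift Additive shift of total GC probability in positives
#'   (0 = none).
#' @param seed Integer seed; generation is fully deterministic.
#' @return A `synth_config` object.
#' @export
synth_config <- function(n_pos = 518L, n_neg = 1072L,
                         length_range = c(200L, 3000L),
                         base_probs = c(A = 0.25, C = 0.25, G = 0.25,
                                        T = 0.25),
                         motifs = DEFAULT_MOTIFS, plant_rate = 1.0,
                         gc_shift = 0, seed = 1L) {
  stopifnot(n_pos >= 1L, n_neg >= 1L, length(length_range) == 2L,
            length_range[1] >= 1L, length_range[2] >= length_range[1],
            length(base_probs) == 4L, abs(sum(base_probs) - 1) < 1e-9,
            all(base_probs > 0), plant_rate >= 0,
            all(nchar(motifs) >= 1L), length(motifs) >= 1L)
  if (max(nchar(motifs)) > length_range[1])
    stop("motif longer than the minimum sequence length")
  gc <- base_probs[["C"]] + base_probs[["G"]]
  if (gc + gc_shift <= 0 || gc + gc_shift >= 1)
    stop("gc_shift pushes GC probability outside (0, 1)")
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 length_range = as.integer(length_range),
                 base_probs = base_probs, motifs = toupper(motifs),
                 plant_rate = plant_rate, gc_shift = gc_shift,
                 seed = as.integer(seed)),
            class = "synth_config")
}

shift_gc <- function(p, delta) {
  if (delta == 0) return(p)
  gc <- p[["C"]] + p[["G"]]; at <- 1 - gc
  c(A = p[["A"]] * (at - delta) / at, C = p[["C"]] * (gc + delta) / gc,
    G = p[["G"]] * (gc + delta) / gc, T = p[["T"]] * (at - delta) / at)
}

random_seq <- function(L, probs)
  paste(sample(BASES, L, replace = TRUE, prob = probs), collapse = "")

# non-overlapping motif planting by overwrite; returns seq + loci table
plant_motifs <- function(seq, motifs, n_loci) {
  L <- nchar(seq)
  mlen <- nchar(motifs[1])
  if (n_loci == 0L)
    return(list(seq = seq,
                loci = data.frame(start = integer(0),
                                  motif = character(0))))
  starts <- sample.int(L - mlen + 1L)
  chosen <- integer(0)
  for (s in starts) {
    if (length(chosen) >= n_loci) break
    if (all(abs(s - chosen) >= mlen)) chosen <- c(chosen, s)
  }
  which_motif <- sample.int(length(motifs), length(chosen),
                            replace = TRUE)
  for (i in seq_along(chosen)) {
    substr(seq, chosen[i], chosen[i] + mlen - 1L) <- motifs[which_motif[i]]
  }
  ord <- order(chosen)
  list(seq = seq, loci = data.frame(start = chosen[ord],
                                    motif = motifs[which_motif][ord]))
}

#' Generate a labeled synthetic dataset
#'
#' Positives carry the configured compositional signal (planted motifs
#' at `Poisson(plant_rate * L / 100)` non-overlapping loci, clipped to
#' what fits, and/or a GC shift); negatives are pure background. The
#' planted-locus truth is attached as attribute `"truth"`.
#'
#' @param cfg A [synth_config()].
#' @return A `gene_dataset` of `n_pos + n_neg` records (positives
#'   first), with a `truth` attribute listing planted loci per record.
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  mlen <- nchar(cfg$motifs[1])
  if (length(unique(nchar(cfg$motifs))) != 1L)
    stop("all motifs must have equal length")
  pos_probs <- shift_gc(cfg$base_probs, cfg$gc_shift)
  n <- cfg$n_pos + cfg$n_neg
  # lengths are drawn up-front so the length distribution depends only on
  # (seed, class sizes, range), never on the signal settings
  span <- cfg$length_range[2] - cfg$length_range[1] + 1L
  lens <- cfg$length_range[1] + sample.int(span, n, replace = TRUE) - 1L
  records <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(cfg$n_pos)) {
    L <- lens[i]
    seq <- random_seq(L, pos_probs)
    n_loci <- stats::rpois(1L, cfg$plant_rate * L / 100)
    planted <- plant_motifs(seq, cfg$motifs, n_loci)
    records[[i]] <- gene_sequence(sprintf("pos_%04d", i), planted$seq,
                                  label = 1)
    truth[[i]] <- planted$loci
  }
  for (i in seq_len(cfg$n_neg)) {
    j <- cfg$n_pos + i
    records[[j]] <- gene_sequence(sprintf("neg_%04d", i),
                                  random_seq(lens[j], cfg$base_probs),
                                  label = 0)
    truth[[j]] <- data.frame(start = integer(0), motif = character(0))
  }
  ds <- gene_dataset(records)
  names(truth) <- dataset_ids(ds)
  attr(ds, "truth") <- truth
  attr(ds, "config") <- cfg
  ds
}

#' Summarize the planted class signal of a generated dataset
#'
#' Counts planted loci per class from the generation truth and reports
#' the closed-form background expectation of chance motif occurrences
#' (`(L - m + 1) / 4^m` per motif for a uniform background).
#'
#' @param dataset A dataset from [generate_dataset()].
#' @return List with per-class planted-locus counts and the expected
#'   background occurrence rate per sequence.
#' @export
expected_separability <- function(dataset) {
  truth <- attr(dataset, "truth")
  cfg <- attr(dataset, "config")
  if (is.null(truth) || is.null(cfg))
    stop("dataset carries no generation truth")
  labels <- dataset_labels(dataset)
  planted <- vapply(truth, nrow, integer(1))
  lens <- dataset_lengths(dataset)
  mlen <- nchar(cfg$motifs[1])
  bg_per_seq <- (lens - mlen + 1) * length(cfg$motifs) / 4^mlen
  list(planted_pos = sum(planted[labels == 1L]),
       planted_neg = sum(planted[labels == 0L]),
       mean_planted_pos = mean(planted[labels == 1L]),
       mean_background_occurrences = mean(bg_per_seq),
       plant_rate = cfg$plant_rate)
}

#' Write a synthetic dataset as a FASTA pair plus truth JSON
#'
#' @param dataset A dataset from [generate_dataset()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_synthetic <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  labels <- dataset_labels(dataset)
  paths <- c(pos = file.path(dir, "positives.fasta"),
             neg = file.path(dir, "negatives.fasta"),
             truth = file.path(dir, "truth.json"))
  write_fasta(dataset$records[labels == 1L], paths[["pos"]])
  write_fasta(dataset$records[labels == 0L], paths[["neg"]])
  truth <- attr(dataset, "truth")
  jsonlite::write_json(truth, paths[["truth"]], dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
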