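#' Tokenize a DNA sequence into overlapping n-gram sub-words
#'
#' Splits a sequence into its "sentence" of biological sub-words: all
#' overlapping substrings of length `n` at stride 1, so a clean sequence
#' of length L yields L - n + 1 tokens. Tokens containing `N` are
#' omitted. A sequence shorter than `n` yields an empty sentence.
#'
#' @param seq A `gene_sequence`, or a character scalar over `A/C/G/T/N`.
#' @param n Token length (the n-gram level; the tuned default elsewhere
#'   in the package is 6).
#' @return Character vector of tokens.
#' @export
tokenize <- function(seq, n = 6L) {
  if (inherits(seq, "gene_sequence")) seq <- seq$seq
  stopifnot(is.character(seq), length(seq) == 1L)
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  L <- nchar(seq)
  if (L < n) return(character(0))
  starts <- seq_len(L - n + 1L)
  tokens <- substring(seq, starts, starts + n - 1L)
  tokens[!grepl("N", tokens, fixed = TRUE)]
}

#' Write a token corpus file for embedding training
#'
#' One line per sequence, tokens space-separated, in dataset record
#' order (the plain-text one-sentence-per-line dialect used by fastText
#' style trainers).
#'
#' @param dataset A `gene_dataset`.
#' @param path Output path.
#' @param n Token length.
#' @return `path`, invisibly.
#' @export
build_corpus <- function(dataset, path, n = 6L) {
  sentences <- corpus_sentences(dataset, n)
  writeLines(vapply(sentences, paste, character(1), collapse = " "), path)
  invisible(path)
}

# in-memory sentence list; shared by build_corpus and featurize_dataset
corpus_sentences <- function(dataset, n = 6L) {
  if (length(dataset$records) == 0L) stop("dataset is empty")
  sentences <- lapply(dataset_seqs(dataset), tokenize, n = n)
  if (all(lengths(sentences) == 0L))
    stop("all sentences are empty (every sequence shorter than n = ", n,
         " or fully ambiguous)")
  sentences
}

#' Read a token corpus file back into sentences
#'
#' @param path Corpus file written by [build_corpus()].
#' @return List of character vectors (one sentence per line).
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lapply(lines, function(l) {
    if (!nzchar(l)) character(0) else strsplit(l, " ", fixed = TRUE)[[1]]
  })
}
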