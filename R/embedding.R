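#' Embedding hyperparameters
#'
#' Parameters of the sub-word CBOW language model. Defaults follow the
#' tuned configuration used throughout the package: 6-gram tokens,
#' 100-dimensional vectors, context window 5, 200 epochs, learning rate
#' 0.1 with linear decay, softmax loss.
#'
#' @param n Token length (n-gram level).
#' @param dim Embedding dimension.
#' @param ws Context window half-width (tokens each side).
#' @param epochs Number of passes over the corpus.
#' @param lr Initial learning rate (linear decay to `1e-4 * lr`).
#' @param loss One of `"softmax"` (full softmax over the vocabulary),
#'   `"hs"` (hierarchical softmax over a frequency-built Huffman tree) or
#'   `"ns"` (negative sampling). Softmax cost scales with the vocabulary
#'   (4^n); `hs`/`ns` are the practical choices at n = 6.
#' @param negatives Negatives per target for `loss = "ns"`
#'   (unigram^0.75 sampling table).
#' @param seed Integer seed; training is single-worker and
#'   bit-reproducible given the seed.
#' @return An `embedding_params` object.
#' @export
embedding_params <- function(n = 6L, dim = 100L, ws = 5L, epochs = 200L,
                             lr = 0.1, loss = c("softmax", "hs", "ns"),
                             negatives = 5L, seed = 1L) {
  loss <- match.arg(loss)
  n <- as.integer(n); dim <- as.integer(dim); ws <- as.integer(ws)
  epochs <- as.integer(epochs)
  stopifnot(n >= 1L, dim >= 1L, ws >= 1L, epochs >= 0L, lr > 0,
            negatives >= 1L)
  structure(list(n = n, dim = dim, ws = ws, epochs = epochs, lr = lr,
                 loss = loss, negatives = as.integer(negatives),
                 seed = as.integer(seed)),
            class = "embedding_params")
}

loss_code <- function(loss) match(loss, c("softmax", "hs", "ns")) - 1L

# deterministic initial input vectors, uniform(-1/dim, 1/dim)
init_input_vectors <- function(vocab_size, dim, seed) {
  set.seed(seed)
  matrix(stats::runif(dim * vocab_size, -1 / dim, 1 / dim),
         nrow = dim, ncol = vocab_size)
}

#' Train a CBOW sub-word embedding model
#'
#' Continuous bag-of-words: each token is predicted from the mean input
#' vector of its windowed context, optimizing the configured loss by
#' single-worker SGD with a linearly decaying learning rate. Determinism
#' is guaranteed under a fixed seed.
#'
#' @param corpus A corpus file path (as written by [build_corpus()]) or a
#'   list of token sentences.
#' @param params An [embedding_params()] object.
#' @return An `embedding_model`: `vocab` (token vector, index order),
#'   `vectors` (|vocab| x dim input-vector matrix, rownames = tokens),
#'   `output` (output-weight matrix), `params`.
#' @export
train_embedding <- function(corpus, params = embedding_params()) {
  sentences <- if (is.character(corpus)) read_corpus(corpus) else corpus
  if (length(sentences) == 0L || all(lengths(sentences) == 0L))
    stop("corpus is empty")
  lens <- nchar(unlist(sentences, use.names = FALSE))
  if (length(lens) && any(lens != params$n))
    stop("corpus token length does not match params$n = ", params$n)
  vocab <- sort(unique(unlist(sentences, use.names = FALSE)))
  if (length(vocab) < 2L)
    stop("vocabulary has fewer than 2 tokens; cannot train")
  idx <- lapply(sentences, function(s) match(s, vocab) - 1L)
  U0 <- init_input_vectors(length(vocab), params$dim, params$seed)
  fit <- cbow_train_cpp(idx, U0, params$ws, params$epochs, params$lr,
                        loss_code(params$loss), params$negatives,
                        as.double(params$seed))
  vectors <- t(fit$input)
  rownames(vectors) <- vocab
  structure(list(vocab = vocab, vectors = vectors,
                 output = t(fit$output), params = params),
            class = "embedding_model")
}

#' @export
print.embedding_model <- function(x, ...) {
  cat("embedding_model:", length(x$vocab), "tokens x", x$params$dim,
      "dims (", x$params$n, "-grams, loss =", x$params$loss, ")\n")
  invisible(x)
}

#' Embed a token sentence as a fixed-length sequence vector
#'
#' The sequence vector is the unweighted mean of the input vectors of
#' in-vocabulary tokens, so sequences of any length map to vectors of
#' identical dimension. Out-of-vocabulary tokens are skipped; an empty
#' or fully out-of-vocabulary sentence yields the zero vector with a
#' warning.
#'
#' @param model An `embedding_model`.
#' @param sentence Character vector of tokens (see [tokenize()]).
#' @return Numeric vector of length `model$params$dim`.
#' @export
vectorize <- function(model, sentence) {
  stopifnot(inherits(model, "embedding_model"))
  hit <- match(sentence, model$vocab)
  hit <- hit[!is.na(hit)]
  if (length(hit) == 0L) {
    warning("sentence has no in-vocabulary tokens; returning zero vector")
    return(numeric(model$params$dim))
  }
  colMeans(model$vectors[hit, , drop = FALSE])
}

#' Featurize a labeled dataset with sub-word embeddings
#'
#' Tokenizes every record, trains (or reuses) an embedding model on the
#' full unlabeled corpus, and returns the n_records x dim feature matrix
#' of mean token vectors with the aligned 0/1 label vector. Training on
#' the full corpus is unsupervised and carries no label leakage.
#'
#' @param dataset A `gene_dataset`.
#' @param params An [embedding_params()].
#' @param model Optional pre-trained `embedding_model` to reuse.
#' @return List with `X` (matrix, rownames = ids), `y` (integer labels)
#'   and `model`.
#' @export
featurize_dataset <- function(dataset, params = embedding_params(),
                              model = NULL) {
  sentences <- corpus_sentences(dataset, params$n)
  if (is.null(model)) model <- train_embedding(sentences, params)
  X <- t(vapply(sentences, function(s) {
    hit <- match(s, model$vocab)
    hit <- hit[!is.na(hit)]
    if (length(hit) == 0L) numeric(model$params$dim)
    else colMeans(model$vectors[hit, , drop = FALSE])
  }, numeric(model$params$dim)))
  rownames(X) <- dataset_ids(dataset)
  list(X = X, y = dataset_labels(dataset), model = model)
}

#' Save an embedding model as plain text
#'
#' Header line `token_length dim window epochs lr loss negatives seed`,
#' then one `token v1 ... v_dim` line per vocabulary entry (the common
#' text vector-table format).
#'
#' @param model An `embedding_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_embedding <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  p <- model$params
  writeLines(paste(p$n, p$dim, p$ws, p$epochs, p$lr, p$loss, p$negatives,
                   p$seed), con)
  rows <- vapply(seq_along(model$vocab), function(i) {
    paste(model$vocab[i],
          paste(formatC(model$vectors[i, ], format = "g", digits = 17),
                collapse = " "))
  }, character(1))
  writeLines(rows, con)
  invisible(path)
}

#' Load an embedding model saved by [save_embedding()]
#'
#' @param path Path to a saved model.
#' @return An `embedding_model` (without output weights; sufficient for
#'   vectorization).
#' @export
load_embedding <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- strsplit(lines[1], " ", fixed = TRUE)[[1]]
  params <- embedding_params(n = as.integer(hdr[1]), dim = as.integer(hdr[2]),
                             ws = as.integer(hdr[3]),
                             epochs = as.integer(hdr[4]),
                             lr = as.numeric(hdr[5]), loss = hdr[6],
                             negatives = as.integer(hdr[7]),
                             seed = as.integer(hdr[8]))
  parts <- strsplit(lines[-1], " ", fixed = TRUE)
  vocab <- vapply(parts, `[`, character(1), 1L)
  vectors <- do.call(rbind, lapply(parts, function(p) as.numeric(p[-1])))
  rownames(vectors) <- vocab
  structure(list(vocab = vocab, vectors = vectors, output = NULL,
                 params = params),
            class = "embedding_model")
}
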