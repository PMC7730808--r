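# small deterministic corpora keep these fast; the full-scale behaviour is
# exercised by the end-to-end acceptance tests

toy_sentences <- function() {
  # two disjoint context cohorts: {AAA, AAC, CCC, CCA} tokens only ever
  # co-occur with each other, likewise {GGG, GGT, TTT, TTG}
  coh1 <- c("AAA", "AAC", "CCC", "CCA")
  coh2 <- c("GGG", "GGT", "TTT", "TTG")
  set.seed(7)
  sents <- c(lapply(1:60, function(i) sample(coh1, 8, TRUE)),
             lapply(1:60, function(i) sample(coh2, 8, TRUE)))
  sents[sample(length(sents))]
}

test_that("zero training epochs return the seeded initialization", {
  sents <- toy_sentences()
  p <- embedding_params(n = 3, dim = 4, ws = 2, epochs = 0, seed = 11)
  m <- train_embedding(sents, p)
  vocab <- sort(unique(unlist(sents)))
  init <- t(essembler:::init_input_vectors(length(vocab), 4L, 11L))
  rownames(init) <- vocab
  expect_equal(m$vectors, init)
})

test_that("training is bit-reproducible under a fixed seed", {
  sents <- toy_sentences()
  for (loss in c("softmax", "hs", "ns")) {
    p <- embedding_params(n = 3, dim = 8, ws = 2, epochs = 3, loss = loss,
                          seed = 5)
    m1 <- train_embedding(sents, p)
    m2 <- train_embedding(sents, p)
    expect_identical(m1$vectors, m2$vectors)
    p2 <- p; p2$seed <- 6L
    m3 <- train_embedding(sents, p2)
    expect_false(identical(m1$vectors, m3$vectors))
  }
})

test_that("context cohorts separate in cosine similarity, agreeing with PMI", {
  sents <- toy_sentences()
  p <- embedding_params(n = 3, dim = 16, ws = 3, epochs = 60, lr = 0.1,
                        loss = "softmax", seed = 3)
  m <- train_embedding(sents, p)
  cosine <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  v <- function(tok) m$vectors[tok, ]
  expect_gt(cosine(v("AAA"), v("CCC")), cosine(v("AAA"), v("GGG")))
  expect_gt(cosine(v("GGG"), v("TTT")), cosine(v("GGG"), v("CCC")))

  # PMI oracle: within-cohort pairs co-occur, across-cohort pairs do not
  vocab <- m$vocab
  cooc <- matrix(0, length(vocab), length(vocab),
                 dimnames = list(vocab, vocab))
  for (s in sents)
    for (i in seq_along(s))
      for (j in seq_along(s))
        if (i != j) cooc[s[i], s[j]] <- cooc[s[i], s[j]] + 1
  expect_gt(cooc["AAA", "CCC"], 0)
  expect_equal(unname(cooc["AAA", "GGG"]), 0)
})

test_that("softmax vocabulary gradient matches finite differences", {
  sents <- list(c(0L, 1L, 2L, 1L, 0L), c(2L, 0L, 1L), c(1L, 2L, 0L, 2L))
  set.seed(2)
  U <- matrix(rnorm(6, sd = 0.3), 2, 3)
  W <- matrix(rnorm(6, sd = 0.3), 2, 3)
  g <- essembler:::cbow_loss_grad_cpp(sents, U, W, 2L, 0L)
  num_grad <- function(M, which) {
    out <- M * 0
    h <- 1e-6
    for (i in seq_along(M)) {
      up <- M; up[i] <- up[i] + h
      dn <- M; dn[i] <- dn[i] - h
      lu <- if (which == "U")
        essembler:::cbow_loss_grad_cpp(sents, up, W, 2L, 0L)$loss
      else essembler:::cbow_loss_grad_cpp(sents, U, up, 2L, 0L)$loss
      ld <- if (which == "U")
        essembler:::cbow_loss_grad_cpp(sents, dn, W, 2L, 0L)$loss
      else essembler:::cbow_loss_grad_cpp(sents, U, dn, 2L, 0L)$loss
      out[i] <- (lu - ld) / (2 * h)
    }
    out
  }
  expect_lt(max(abs(num_grad(U, "U") - g$dU)) / max(abs(g$dU)), 1e-5)
  expect_lt(max(abs(num_grad(W, "W") - g$dW)) / max(abs(g$dW)), 1e-5)
})

test_that("sequence vectors are token-mean based and length-invariant", {
  sents <- toy_sentences()
  m <- train_embedding(sents, embedding_params(n = 3, dim = 8, ws = 2,
                                               epochs = 5, seed = 1))
  t1 <- m$vocab[1]
  expect_equal(vectorize(m, t1), unname(m$vectors[t1, ]),
               ignore_attr = TRUE)
  expect_equal(vectorize(m, rep(t1, 3)), vectorize(m, t1))
  # antisymmetric construction cancels exactly
  m2 <- m
  m2$vectors["AAA", ] <- c(1, -2, 3, 0.5, -1, 2, 0, 4)
  m2$vectors["CCC", ] <- -m2$vectors["AAA", ]
  expect_equal(unname(vectorize(m2, c("AAA", "CCC"))), rep(0, 8))
  expect_warning(z <- vectorize(m, c("NOTATOKEN")), "no in-vocabulary")
  expect_equal(z, rep(0, 8))
  # vectors have the model dimension whatever the sentence length
  expect_length(vectorize(m, m$vocab), 8L)
})

test_that("dataset featurization aligns rows with records and permutes with them", {
  ds <- small_motif_dataset(n_pos = 6, n_neg = 6, lengths = c(60L, 120L))
  p <- embedding_params(n = 4, dim = 10, ws = 2, epochs = 4, seed = 9)
  feat <- featurize_dataset(ds, p)
  expect_equal(dim(feat$X), c(12L, 10L))
  expect_equal(feat$y, vapply(ds$records, `[[`, integer(1), "label"))
  # permuting records permutes rows identically (reusing the same model)
  set.seed(4)
  perm <- sample(12L)
  dsp <- gene_dataset(ds$records[perm])
  featp <- featurize_dataset(dsp, p, model = feat$model)
  expect_equal(featp$X, feat$X[perm, ])
})

test_that("embedding models persist through the text format", {
  sents <- toy_sentences()
  m <- train_embedding(sents, embedding_params(n = 3, dim = 6, ws = 2,
                                               epochs = 3, seed = 8))
  path <- withr::local_tempfile(fileext = ".vec")
  save_embedding(m, path)
  m2 <- load_embedding(path)
  expect_equal(m2$vocab, m$vocab)
  expect_equal(m2$vectors, m$vectors, tolerance = 1e-15)
  expect_equal(m2$params$dim, m$params$dim)
})

test_that("undersized vocabularies are rejected", {
  expect_error(train_embedding(list(rep("AAA", 5)),
                               embedding_params(n = 3, dim = 2, epochs = 1)),
               "fewer than 2")
})
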