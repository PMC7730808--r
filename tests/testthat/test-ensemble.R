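test_that("meta-feature matrices hold out-of-fold probabilities", {
  d <- noisy_2d(n = 100, seed = 1)
  spec <- cheap_ensemble(seed = 2)
  meta <- make_meta_features(spec, d$X, d$y)
  expect_equal(dim(meta), c(100L, 2L))
  expect_true(all(meta >= 0 & meta <= 1))
  # permuting samples permutes meta rows identically
  set.seed(3)
  perm <- sample(100L)
  # (fold assignment depends on order, so compare against a member with a
  #  deterministic oof output: wide-margin kNN k=1 reproduces y exactly)
  sep <- separable_2d(n = 100, gap = 10, seed = 4)
  spec1 <- ensemble_spec(list(classifier_spec("knn", list(k = 1))), seed = 5)
  m1 <- make_meta_features(spec1, sep$X, sep$y)
  expect_equal(as.numeric(m1), as.numeric(sep$y))
  m1p <- make_meta_features(spec1, sep$X[perm, ], sep$y[perm])
  expect_equal(as.numeric(m1p), as.numeric(sep$y[perm]))
})

test_that("the OLS meta-learner reproduces a perfect member exactly", {
  set.seed(6)
  y <- rep(c(0L, 1L), each = 25)
  meta <- cbind(perfect = as.numeric(y))
  beta <- essembler:::fit_meta(meta, y)
  pred <- pmin(pmax(beta[1] + meta %*% beta[-1], 0), 1)
  expect_equal(as.numeric(pred), as.numeric(y), tolerance = 1e-10)
  expect_equal(mean(as.integer(pred >= 0.5) == y), 1.0)
})

test_that("collinear members fall back to ridge with matching predictions", {
  set.seed(7)
  y <- rep(c(0L, 1L), each = 30)
  p1 <- pmin(pmax(y + rnorm(60, sd = 0.2), 0), 1)
  single <- cbind(p1)
  dup <- cbind(p1, p1)
  b1 <- essembler:::fit_meta(single, y)
  expect_warning(b2 <- essembler:::fit_meta(dup, y), "ridge")
  pred1 <- b1[1] + single %*% b1[-1]
  pred2 <- b2[1] + dup %*% b2[-1]
  expect_equal(as.numeric(pred1), as.numeric(pred2), tolerance = 1e-6)
})

test_that("uninformative members collapse to the class prevalence", {
  y <- c(rep(1L, 20), rep(0L, 60))
  meta <- matrix(0.5, 80, 2)
  expect_warning(beta <- essembler:::fit_meta(meta, y), "ridge")
  pred <- beta[1] + meta %*% beta[-1]
  expect_equal(as.numeric(pred), rep(mean(y), 80), tolerance = 1e-4)
})

test_that("scores clip to [0, 1] and the threshold boundary labels 1", {
  d <- separable_2d(n = 60, gap = 8, seed = 8)
  model <- fit_ensemble(ensemble_spec(list(classifier_spec("knn", list(k = 1))),
                                      seed = 9), d$X, d$y)
  # force a degenerate meta-learner whose score sits exactly on the
  # threshold for every sample
  model$beta <- c(0.5, 0)
  pr <- predict(model, d$X)
  expect_true(all(pr$score == 0.5))
  expect_true(all(pr$label == 1L))
  model$beta <- c(2, 3)
  expect_true(all(predict(model, d$X)$score <= 1))
  model$beta <- c(-2, 0)
  expect_true(all(predict(model, d$X)$score >= 0))
})

test_that("ensemble scores are monotone in a positively weighted member", {
  d <- noisy_2d(n = 120, seed = 10)
  model <- fit_ensemble(ensemble_spec(list(classifier_spec("svm")),
                                      seed = 11), d$X, d$y)
  expect_gt(model$beta[2], 0)
  p_member <- predict_proba(model$members[[1]], d$X)
  score <- predict_proba(model, d$X)
  # non-decreasing in the member probability (clipping may create ties)
  expect_true(all(diff(score[order(p_member)]) >= 0))
})

test_that("a single-member ensemble preserves that member's AUC exactly", {
  d <- noisy_2d(n = 160, shift = 1.2, seed = 12)
  set.seed(12)
  te <- sort(c(sample(which(d$y == 0), 20), sample(which(d$y == 1), 20)))
  tr <- setdiff(seq_len(160), te)
  model <- fit_ensemble(ensemble_spec(list(classifier_spec("svm")),
                                      seed = 13),
                        d$X[tr, ], d$y[tr])
  member_auc <- auc_rank(predict_proba(model$members[[1]],
                                       d$X[te, ]), d$y[te])
  ens_auc <- auc_rank(predict_proba(model, d$X[te, ]), d$y[te])
  expect_identical(ens_auc, member_auc)
})

test_that("stacking does not fall below its best member on motif data", {
  # scaled-down version of the end-to-end property: cheap members,
  # k-mer features, three seeds
  for (seed in 1:3) {
    ds <- small_motif_dataset(n_pos = 40, n_neg = 80, plant_rate = 2,
                              seed = seed)
    feat <- featurize_baseline(ds, function(s) kmer_counts(s, 3))
    rep <- run_cv(ds, feat, cheap_ensemble(seed = seed),
                  cv_plan(120, k = 3, repeats = 1, seed = seed))
    s <- rep$summary
    ens <- s$mean[s$metric == "auc"]
    members <- s$mean[grepl("^auc_", s$metric)]
    expect_gte(ens, max(members) - 0.02)
  }
})
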