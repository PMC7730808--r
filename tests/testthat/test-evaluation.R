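test_that("confusion counts match a per-element counting oracle", {
  cc <- confusion(c(1, 0, 1, 0), c(1, 0, 1, 0))
  expect_equal(unlist(cc[c("TP", "TN", "FP", "FN")]),
               c(TP = 2L, TN = 2L, FP = 0L, FN = 0L))
  # flipping predictions swaps TP<->FN and TN<->FP
  cc2 <- confusion(c(1, 0, 1, 0), c(0, 1, 0, 1))
  expect_equal(cc2$FN, cc$TP)
  expect_equal(cc2$FP, cc$TN)

  set.seed(1)
  y <- sample(0:1, 1000, replace = TRUE)
  p <- sample(0:1, 1000, replace = TRUE)
  oracle <- c(TP = 0L, TN = 0L, FP = 0L, FN = 0L)
  for (i in seq_along(y)) {
    if (y[i] == 1 && p[i] == 1) oracle["TP"] <- oracle["TP"] + 1L
    if (y[i] == 0 && p[i] == 0) oracle["TN"] <- oracle["TN"] + 1L
    if (y[i] == 0 && p[i] == 1) oracle["FP"] <- oracle["FP"] + 1L
    if (y[i] == 1 && p[i] == 0) oracle["FN"] <- oracle["FN"] + 1L
  }
  cc3 <- confusion(y, p)
  expect_equal(unlist(cc3[c("TP", "TN", "FP", "FN")]), oracle)
  expect_error(confusion(c(1, 0), c(1)), "length")
  expect_error(confusion(integer(0), integer(0)), "empty")
})

test_that("metric formulas evaluate exactly on known tables", {
  cc <- structure(list(TP = 3L, TN = 4L, FP = 1L, FN = 2L),
                  class = "confusion_counts")
  m <- classification_metrics(cc)
  expect_equal(m$mcc, 10 / sqrt(600), tolerance = 1e-12)
  expect_equal(m$sens, 100 * 3 / 5)
  expect_equal(m$spec, 100 * 4 / 5)
  expect_equal(m$acc, 100 * 7 / 10)

  perfect <- confusion(c(1, 1, 0, 0), c(1, 1, 0, 0))
  mp <- classification_metrics(perfect, scores = c(0.9, 0.8, 0.1, 0.2),
                               labels = c(1, 1, 0, 0))
  expect_equal(mp$sens, 100)
  expect_equal(mp$spec, 100)
  expect_equal(mp$acc, 100)
  expect_equal(mp$mcc, 1)
  expect_equal(mp$auc, 1)

  # degenerate denominators use the MCC = 0 convention
  allpos <- confusion(c(1, 0, 1), c(1, 1, 1))
  expect_equal(classification_metrics(allpos)$mcc, 0)
})

test_that("rank AUC equals all-pairs concordance and handles ties", {
  expect_equal(auc_rank(rep(0.3, 10), rep(c(0, 1), 5)), 0.5)
  set.seed(2)
  for (i in 1:5) {
    n <- sample(20:120, 1)
    y <- rbinom(n, 1, 0.4)
    if (sum(y) == 0 || sum(y) == n) next
    s <- round(runif(n), 2)  # rounding forces ties
    pairs <- 0; conc <- 0
    for (a in which(y == 1)) for (b in which(y == 0)) {
      pairs <- pairs + 1
      conc <- conc + (s[a] > s[b]) + 0.5 * (s[a] == s[b])
    }
    expect_equal(auc_rank(s, y), conc / pairs, tolerance = 1e-12)
  }
  expect_error(auc_rank(1:3, c(1, 1, 1)), "both classes")
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(3)
  y <- rbinom(300, 1, 0.35)
  s <- runif(300) + 0.4 * y
  expect_equal(auc_rank(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("fold plans are disjoint, exhaustive and balanced", {
  for (strat in c(FALSE, TRUE)) {
    plan <- cv_plan(1590, k = 5, repeats = 10, stratified = strat,
                    seed = 7)
    labels <- rep(c(1L, 0L), c(518, 1072))
    assigns <- fold_assignments(plan, labels)
    expect_length(assigns, 10L)
    for (f in assigns) {
      expect_length(f, 1590L)
      expect_setequal(unique(f), 1:5)
      if (strat) {
        # class balance per fold, overall size within one of 318
        expect_lte(diff(range(table(f[labels == 1]))), 1L)
        expect_lte(diff(range(table(f[labels == 0]))), 1L)
        expect_true(all(abs(table(f) - 318L) <= 1L))
      } else {
        expect_true(all(table(f) == 318L))
      }
    }
  }
  # odd n: sizes differ by at most one
  plan2 <- cv_plan(103, k = 5, repeats = 3, seed = 8)
  for (f in fold_assignments(plan2))
    expect_lte(diff(range(table(f))), 1L)
})

test_that("cross-validation is deterministic and leakage-guarded", {
  ds <- small_motif_dataset(n_pos = 30, n_neg = 60, plant_rate = 2,
                            seed = 14)
  feat <- featurize_baseline(ds, function(s) kmer_counts(s, 3))
  plan <- cv_plan(90, k = 5, repeats = 2, seed = 21)
  r1 <- run_cv(ds, feat, classifier_spec("svm"), plan,
               smote = smote_config(seed = 1))
  r2 <- run_cv(ds, feat, classifier_spec("svm"), plan,
               smote = smote_config(seed = 1))
  expect_identical(serialize(r1, NULL), serialize(r2, NULL))
  # no augmented training row ever equals a held-out row
  for (cell in r1$manifest$smote_audit)
    expect_length(intersect(cell$train_keys, cell$test_keys), 0L)
  # writing reports twice yields byte-identical files
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_report(r1, d1); write_report(r2, d2)
  for (f in c("per_fold.tsv", "report.json"))
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
})

test_that("single-class folds raise an actionable error", {
  recs <- c(lapply(1:2, function(i)
    gene_sequence(paste0("p", i), random_dna(60), label = 1)),
    lapply(1:28, function(i)
      gene_sequence(paste0("n", i), random_dna(60), label = 0)))
  ds <- gene_dataset(recs)
  feat <- featurize_baseline(ds, function(s) kmer_counts(s, 2))
  plan <- cv_plan(30, k = 5, repeats = 1, seed = 1)
  expect_error(run_cv(ds, feat, classifier_spec("knn"), plan),
               "stratified")
})
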