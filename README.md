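# essembler

Essential-gene classification from DNA sequence alone, via sub-word
embeddings and a stacked ensemble.

## The problem

Essential genes — the genes an organism cannot survive without — are
usually identified by knockout experiments that are slow and costly.
Sequence-only classifiers sidestep the need for expression, network or
homology data: given nothing but nucleotide sequences labeled
essential / non-essential, they learn compositional signatures of
essentiality. `essembler` implements such a pipeline end to end:

1. **Tokenization** — each DNA sequence becomes a "sentence" of
   overlapping n-gram sub-words (default hexamers): a sequence of
   length *L* yields *L − n + 1* tokens.
2. **Embedding** — a continuous bag-of-words (CBOW) language model,
   written from scratch and bit-reproducible under a seed, learns a
   vector per token (dim = 100, window = 5; softmax, hierarchical
   softmax or negative-sampling loss). A sequence is represented by
   the unweighted mean of its token vectors — a fixed-length feature
   vector whatever the sequence length.
3. **Classification** — five base learners behind one contract
   (kNN *k* = 10; random forest, 500 trees; RBF-SVM, C = 2¹⁵,
   γ = 2⁻⁹; MLP 100–50 with 50 % dropout and Adam; a 1-D CNN with two
   conv/max-pool blocks, 64 filters, Adadelta), combined by stacked
   generalization: out-of-fold member probabilities feed an OLS linear
   meta-learner,
   *ŝ* = clip(β₀ + Σ βⱼ pⱼ, 0, 1).
4. **Evaluation** — repeated 5-fold cross-validation with
   sensitivity, specificity, accuracy,
   MCC = (TP·TN − FP·FN)/√((TP+FP)(TP+FN)(TN+FP)(TN+FN)),
   and rank-based (Mann–Whitney) AUC; SMOTE oversampling (regular or
   SVM-variant) applied strictly inside training folds.
5. **Baselines & synthetic data** — k-mer and PseKNC featurizers for
   comparison, and a generator of labeled synthetic gene sets with
   planted hexamer motifs so the whole pipeline is testable offline.

See `vignettes/methods.Rmd` for the full model description and design
rationale.

## Worked example

```r
library(essembler)

# 1. simulate a benchmark with a planted compositional signal
cfg <- synth_config(n_pos = 60, n_neg = 120, length_range = c(200, 800),
                    plant_rate = 1.5, seed = 42)
ds <- generate_dataset(cfg)
print(ds)

# 2. embed sequences as mean 4-gram CBOW vectors
feat <- featurize_dataset(ds, embedding_params(n = 4, dim = 32, epochs = 25,
                                               loss = "hs", seed = 42))
print(feat$model)

# 3. cross-validate a stacking ensemble (light members for the example)
report <- run_cv(ds, feat, ensemble_spec(c("knn", "svm"), seed = 42),
                 cv_plan(length(ds), k = 5, repeats = 2, seed = 42))
print(report)
```

Output:

```
gene_dataset: 180 sequences ( 60 positive / 120 negative )
  lengths: 201 - 800 nt (median 497 )
embedding_model: 256 tokens x 32 dims ( 4 -grams, loss = hs )
cv_report: 2 x 5 -fold CV on n = 180
  TP            7.300 +/- 2.359
  TN           22.000 +/- 3.091
  FP            2.000 +/- 1.700
  FN            4.700 +/- 2.111
  sens         60.944 +/- 15.200
  spec         91.621 +/- 6.808
  acc          81.389 +/- 7.058
  mcc           0.567 +/- 0.154
  auc           0.887 +/- 0.048
  auc_knn       0.890 +/- 0.050
  auc_svm       0.865 +/- 0.063
  pooled AUC    0.888
```

Reading this: per 36-sequence held-out fold the ensemble recovers on
average 7.3 of the 12 planted-motif positives (sensitivity 60.9 %)
while keeping specificity at 91.6 %; the threshold-free AUC of 0.89
says the planted hexamer signal is strongly, though not perfectly,
separable at this small training size. The full-strength pipeline
(hexamer tokens, dim 100, MLP + CNN + SVM members) is what the
acceptance script below runs.

The same stages are available from a shell via the bundled CLI
(`system.file("cli", "essembler.R", package = "essembler")`) with
subcommands `synth`, `featurize`, `train`, `predict` and `cv`, a YAML
`--config` option, and manifests recording seeds and input hashes for
every output.

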