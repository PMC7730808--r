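---
title: "Classifying essential genes from DNA sub-word embeddings: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying essential genes from DNA sub-word embeddings: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Essential genes are the genes an organism cannot survive without.
Knocking them out experimentally is slow and expensive, so a
long-standing goal in microbial genomics is to predict essentiality
from information that is always available: the nucleotide sequence
itself. `essembler` implements a sequence-only classification pipeline
for this problem: DNA sequences are treated as sentences of
overlapping n-gram "biological sub-words", embedded with a small
language model, and classified by a stacked ensemble of five base
learners. Everything needed to validate the pipeline — including a
synthetic benchmark generator with a controllable class signal — ships
with the package, so no external database downloads are required.

## From sequence to feature vector

**Tokenization.** A sequence of length $L$ is split into all
overlapping substrings of length $n$ (stride 1), giving $L - n + 1$
tokens. The default $n = 6$ keeps the vocabulary at most
$4^6 = 4096$ tokens while capturing local composition richer than
single bases or codons; the token length is the single most
influential featurization parameter and is exposed everywhere.
Tokens containing `N` are dropped rather than imputed.

**Embedding.** A continuous bag-of-words (CBOW) model predicts each
token from the mean input vector of its windowed context (window
$w_s = 5$ tokens each side). Three output losses are implemented and
selectable: full softmax over the vocabulary (default), hierarchical
softmax over a frequency-built Huffman tree, and negative sampling
(5 negatives from a unigram$^{0.75}$ table). Training is plain SGD
with a linearly decaying learning rate (initial 0.1, floor
$10^{-4}\times$), 200 epochs by default, single worker, and is
bit-reproducible given a seed. Input vectors start at
$\mathcal U(-1/d, 1/d)$, output weights at zero. No frequency pruning
is applied (minimum token count 1): the corpora here are small.

The trainer is written from scratch (Rcpp); its analytic gradients are
verified against central finite differences in the test suite, through
the same code path the SGD loop uses.

**Sequence vectors.** A variable-length sequence becomes the
*unweighted mean* of its token vectors — a fixed $d$-dimensional
vector ($d = 100$ by default) regardless of length. Concatenating
per-token vectors cannot produce equal widths without padding, which
this design deliberately avoids; the mean is the standard sentence
vector of fastText-style models and is what the fixed 100-feature
width downstream implies. Out-of-vocabulary tokens are skipped; a
fully out-of-vocabulary sequence maps to the zero vector with a
warning.

Embeddings are trained on the full corpus (all sequences, no labels).
Because the objective never sees a label, this carries no
train/test leakage; it also matches how unsupervised sequence
embeddings are used in practice.

## Base classifiers

Five learners sit behind one `fit_classifier()` / `predict_proba()`
contract; all return class-1 probabilities.

| kind | architecture / parameters | probability |
|------|---------------------------|-------------|
| `knn` | $k = 10$, Euclidean distance | neighbour vote fraction |
| `rf`  | 500 trees, 20 candidate features per split, Gini | tree-vote fraction |
| `svm` | RBF kernel, $C = 2^{15} = 32768$, $\gamma = 2^{-9} = 0.001953125$ | Platt-scaled decision values |
| `mlp` | dense 100–50, ReLU, 50% dropout, Adam (lr $10^{-3}$), 100 epochs, batch 32, sigmoid output | sigmoid output |
| `cnn` | two conv(kernel 3, 64 filters, same padding)/max-pool(2) blocks, dense 128–64, 10% dropout, Adadelta, softmax output | softmax class-1 output |

Notes on deliberately resolved ambiguities:

* The SVM defaults sit on the usual power-of-two grid:
  $C = 2^{15} = 32768$ and $\gamma = 2^{-9}$; any other values are
  accepted through `classifier_spec("svm", list(cost = ..., gamma = ...))`.
* The random forest's per-split feature count defaults to 20; the
  common $\sqrt{p}$ rule is available via `mtry = "sqrt"`.
* kNN distance ties break by the smaller training index, making
  predictions deterministic; an exact 5–5 vote records probability
  0.5 and, at the base-classifier level, labels class 0
  (`proba > 0.5` labels 1).
* The CNN input treats the $d$ features as a length-$d$, one-channel
  signal. With kernel order $n = 3$, zero padding $q = 1$ and stride
  $s = 1$, the feature-map length is $(w - n + 2q)/s + 1 = w$;
  each pooling stage halves it (ceiling, with a clipped final window
  so short inputs degrade gracefully). Kernel size, pooling width,
  dense sizes (128–64), batch size (32) and epoch count are this
  package's defaults, chosen as the smallest standard values
  consistent with an eight-layer design.
* The CNN epoch default is 30, balancing convergence against cost on
  feature sets of this width; every fitted MLP/CNN stores its
  per-epoch loss trace (`$epoch_loss`) so convergence can be checked
  on any dataset, and any epoch count can be set via
  `classifier_spec("cnn", list(epochs = ...))`.
* SVM probabilities use a Platt sigmoid fitted on the training
  decision values by the robust Newton iteration. This avoids the
  cross-validated internal calibration of libsvm, whose C-level RNG
  is not seedable from R and would break run-to-run reproducibility.
* MLP/CNN training is mini-batch SGD over shuffled data with
  inverted dropout; both record per-epoch mean loss in the fitted
  model (`$epoch_loss`), which the tests use to assert convergence.

## Stacked generalization

The ensemble (default members MLP + CNN + SVM; the five-member set is
one flag away) is stacked: each member produces *out-of-fold*
probabilities via 5 internal folds, and an ordinary-least-squares
linear meta-learner with intercept is fit on those probabilities
against the labels. Members are then refit on the full training data.
Predictions are $\hat s = \mathrm{clip}(\beta_0 + \sum_j \beta_j p_j,
0, 1)$, labeled 1 when $\hat s \ge$ threshold (default 0.5, boundary
inclusive).

Two design points are worth making explicit:

* Meta-features are out-of-fold by design: resubstitution outputs
  would let the meta-learner reward overfit members, so the standard
  stacked-generalization protocol is used. Internal folds are
  stratified so every internal training set contains both classes
  even under heavy imbalance.
* A singular meta design (e.g. duplicated members) falls back to a
  ridge solve with $\alpha = 10^{-6}$ and a warning; predictions
  coincide with the unpenalized fit wherever that fit is defined.

A single-member ensemble is a positive affine transform of that
member wherever the score is unclipped, so its ranking — hence AUC —
is preserved exactly; the test suite asserts this identity.

## Class imbalance: SMOTE inside the folds

Essential-gene benchmarks are imbalanced (the emulated benchmark has
518 positives to 1072 negatives). `oversample()` implements SMOTE with
two variants:

* **regular** — each synthetic point is
  $x_i + u\,(x_{nn} - x_i)$, $u \sim \mathcal U(0,1)$, between a random
  minority point and one of its $k = 5$ minority nearest neighbours;
  every synthetic point therefore lies on a segment between two
  minority points, which the tests verify by brute force.
* **svm** (default) — synthesis is seeded at the minority-class
  support vectors of an RBF-SVM fit to the training data;
  majority-heavy neighbourhoods interpolate toward minority
  neighbours, minority-dense ones extrapolate away with step bounded
  by half the neighbour distance.

The target minority:majority ratio is 1.0 by default; both it and the
neighbour count are package defaults, configurable in
`smote_config()`. Critically,
oversampling happens **only inside training folds** during
cross-validation; `run_cv()` enforces this structurally and records an
audit trail of exact row keys so the tests can prove that no augmented
training row ever equals a held-out row.

## Evaluation protocol

`run_cv()` implements repeated k-fold cross-validation (default
10 × 5-fold): samples are randomly allocated to five near-equal folds
(sizes within one; allocation is purely random by default, with
optional stratification), each fold is held
out once, and per-fold metrics are averaged across all repeat-fold
cells. Metrics follow the standard confusion-table definitions:
sensitivity $TP/(TP+FN)$, specificity $TN/(TN+FP)$, accuracy
$(TP+TN)/n$ (all in percent), and

$$MCC = \frac{TP \cdot TN - FP \cdot FN}
{\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}},$$

with $MCC = 0$ by convention when any denominator factor vanishes.
AUC uses the rank (Mann–Whitney) formulation with ties counted ½ —
identical to all-pairs concordance, which the tests check exactly.
Because per-fold averaging and pooled-prediction AUC can differ
slightly, both are reported. Every report carries a manifest (seeds,
configuration, fold assignments and their digests) sufficient to
reproduce it bit-for-bit; the same seed yields byte-identical report
files.

## Baseline featurizers

For comparison with composition-based features, the package includes
overlapping k-mer frequencies (`kmer_counts`, default $k=4$,
configurable) and the
pseudo k-tuple nucleotide composition family (`pseknc`): the first
$4^k$ entries are tuple frequencies, followed by $\lambda$ tiered
sequence-order correlation factors weighted by $w$, normalized to sum
to 1. The parallel (Type I) variant pools all properties in a squared
difference; the series (Type II) variant keeps one entry per
(tier, property) pair, $\lambda$ counting total entries in row-major
order. With $\lambda = 0$, or with constant property columns (which
standardization maps to zero), PseKNC reduces exactly to k-mer
composition — both limits are asserted in the tests. The defaults
$\lambda = 10$, $w = 0.5$ are configurable.

Property tables: the bundled defaults are thermodynamic
nearest-neighbour parameters of the 16 dinucleotide steps — unified
enthalpy, entropy and free energy at 37 °C — standardized to mean 0,
sd 1 per property; trinucleotide properties are built additively from
the two constituent steps (the standard nearest-neighbour additivity
construction). These were chosen over the various circulated
"standard" PseKNC index tables because their values are unambiguous
and exactly reproducible; any user table can be supplied as a TSV via
`read_property_table()`, and the structural limits above hold for
every table.

## The synthetic benchmark generator

`generate_dataset()` emulates the *shape* of a microbial essentiality
benchmark: by default 518 positive and 1072 negative sequences with
lengths uniform on 200–3000 nt and i.i.d. background bases. The class
signal is controllable and fully known:

* **motifs** — four fixed hexamers planted in positives at
  $\mathrm{Poisson}(\text{plant\_rate} \cdot L/100)$ non-overlapping
  loci (clipped to what fits), by *overwriting* background bases so
  the length distribution is label-independent and length can never
  act as a confound. Lengths are drawn before any signal is applied,
  so two configurations with the same seed generate identical length
  vectors.
* **gc_shift** — an additive shift of total GC probability in
  positives.

The generator writes standard FASTA pairs plus a truth JSON of planted
loci, and `expected_separability()` summarizes the planted signal
against the closed-form background expectation
$(L - m + 1)\,/\,4^m$ per motif. What the generator does *not*
emulate: codon structure, phylogenetic correlation between genes,
homology clusters, and realistic GC heterogeneity. Passing the
end-to-end tests therefore demonstrates that the pipeline recovers a
planted compositional signal at realistic sizes — not that it attains
any particular accuracy on real essentiality benchmarks, which
additionally carry homology and annotation biases.

## Problem sizes and numerical choices in the shipped validation

The package validates itself at a documented demonstration scale,
chosen so the whole suite runs on a single CPU in well under half an
hour:

* end-to-end run: 250/500 sequences, plant rate 1.0, 6-gram CBOW with
  dim 100 and **50** embedding epochs, default MLP+CNN+SVM stack,
  5-fold CV (single repeat); the null run uses 200/400 sequences with
  no signal.
* the demonstration runs train embeddings with the **hierarchical
  softmax** loss: full softmax over the $4^6$ vocabulary costs
  $\mathcal O(4^n d)$ per token (≈$10^6$ flops here) versus
  $\mathcal O(d \log 4^n)$ for hs, a ~100× difference. Softmax
  remains the API default and is the loss whose gradients are
  finite-difference-checked.
* metric oracles run at full prescribed scale ($10^5$ random
  confusion tables; all-pairs AUC up to $n = 500$), since they are
  cheap.

Other numerical conventions: probabilities are clipped to $[0,1]$
only at the ensemble level; the Platt fit adds $10^{-12}$ to the
Hessian diagonal; softmax computations subtract the row maximum;
log arguments are floored at $10^{-300}$; the embedding learning rate
decays linearly per processed token with a $10^{-4}$ relative floor.

## Known limitations

* The CBOW trainer is single-threaded by design (determinism over
  speed); corpora beyond ~$10^8$ tokens would want a parallel
  implementation.
* Full-softmax training is impractical above small vocabularies
  (n ≤ 4); use `hs` or `ns` for hexamer tokens.
* The SVM-variant SMOTE follows the common support-vector seeding
  heuristic; its "danger/safe" neighbourhood split uses a simple
  majority rule rather than the three-way noise filter of some
  implementations.
* `pseknc` requires unambiguous sequences (no `N`) because the
  correlation terms are defined over consecutive tuples.
* Real-benchmark reproduction (DEG-derived data) is intentionally out
  of scope here; the CLI accepts any FASTA pair, so such data can be
  run when available, but no claims are made about matching published
  numbers on it.
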