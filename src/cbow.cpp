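// Continuous bag-of-words trainer over DNA sub-word sentences.
// Input vectors U are dim x vocab (one column per token); output weights W
// are dim x n_out where n_out = vocab (softmax, negative sampling) or
// vocab - 1 (hierarchical softmax internal nodes). Single-worker SGD with
// linearly decaying learning rate; deterministic under a fixed seed.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

enum LossType { LOSS_SOFTMAX = 0, LOSS_HS = 1, LOSS_NS = 2 };

// splitmix64: portable deterministic RNG independent of compiler stdlib
static inline uint64_t sm64(uint64_t &state) {
  uint64_t z = (state += 0x9e3779b97f4a7c15ULL);
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}
static inline double runif01(uint64_t &state) {
  return (sm64(state) >> 11) * (1.0 / 9007199254740992.0);
}

static inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// Huffman coding of the vocabulary by token frequency (classic two-queue
// construction on counts sorted descending). Fills per-token node paths
// and binary codes.
struct HuffmanCode {
  std::vector<std::vector<int>> points; // internal-node indices, root last
  std::vector<std::vector<int>> codes;  // 0/1 per node on the path
};

static HuffmanCode build_huffman(const std::vector<double> &counts) {
  int V = counts.size();
  std::vector<int> order(V);
  for (int i = 0; i < V; ++i) order[i] = i;
  std::stable_sort(order.begin(), order.end(), [&](int a, int b) {
    return counts[a] > counts[b];
  });
  // count[0..V-1] leaves (descending), then V-1 internal nodes
  std::vector<double> cnt(2 * V - 1, 0.0);
  std::vector<int> parent(2 * V - 1, -1), binary(2 * V - 1, 0);
  for (int i = 0; i < V; ++i) cnt[i] = counts[order[i]];
  int pos1 = V - 1, pos2 = V; // pos1 walks leaves up, pos2 walks new nodes
  for (int a = 0; a < V - 1; ++a) {
    int m1, m2;
    if (pos1 >= 0 && (pos2 >= V + a || cnt[pos1] < cnt[pos2])) m1 = pos1--;
    else m1 = pos2++;
    if (pos1 >= 0 && (pos2 >= V + a || cnt[pos1] < cnt[pos2])) m2 = pos1--;
    else m2 = pos2++;
    cnt[V + a] = cnt[m1] + cnt[m2];
    parent[m1] = V + a;
    parent[m2] = V + a;
    binary[m2] = 1;
  }
  HuffmanCode hc;
  hc.points.assign(V, {});
  hc.codes.assign(V, {});
  for (int i = 0; i < V; ++i) {
    std::vector<int> code, point;
    for (int node = i; parent[node] != -1; node = parent[node]) {
      code.push_back(binary[node]);
      point.push_back(parent[node] - V); // internal-node row in W
    }
    hc.points[order[i]] = point;
    hc.codes[order[i]] = code;
  }
  return hc;
}

// Loss and gradient for one (context, target) pair. h is the context mean.
// Writes gradient wrt h into gh and updates W in place when lr > 0;
// when accumulating (dW != nullptr) adds analytic dL/dW instead.
static double pair_loss_grad(const arma::vec &h, int target, int loss_type,
                             arma::mat &W, double lr, arma::vec &gh,
                             arma::mat *dW, const HuffmanCode *hc,
                             const std::vector<int> *negs) {
  int dim = h.n_elem;
  gh.zeros(dim);
  double loss = 0.0;
  if (loss_type == LOSS_SOFTMAX) {
    arma::vec scores = W.t() * h;            // vocab scores
    double mx = scores.max();
    arma::vec p = arma::exp(scores - mx);
    p /= arma::accu(p);
    loss = -std::log(std::max(p(target), 1e-300));
    arma::vec g = p;
    g(target) -= 1.0;                        // dL/dscore
    gh = W * g;
    if (dW) *dW += h * g.t();
    if (lr > 0) W -= lr * (h * g.t());
  } else if (loss_type == LOSS_HS) {
    const std::vector<int> &point = hc->points[target];
    const std::vector<int> &code = hc->codes[target];
    const double *hp = h.memptr();
    double *ghp = gh.memptr();
    for (size_t b = 0; b < point.size(); ++b) {
      double *wp = W.colptr(point[b]);
      double dot = 0.0;
      for (int k = 0; k < dim; ++k) dot += wp[k] * hp[k];
      double f = sigmoid(dot);
      // code bit 1 means "negative" branch: label = 1 - code
      double label = 1.0 - code[b];
      loss += -std::log(std::max(label > 0.5 ? f : 1.0 - f, 1e-300));
      double g = f - label;                  // dL/d(w.h)
      if (dW) {
        double *dwp = dW->colptr(point[b]);
        for (int k = 0; k < dim; ++k) {
          ghp[k] += g * wp[k];
          dwp[k] += g * hp[k];
        }
      } else {
        for (int k = 0; k < dim; ++k) {
          ghp[k] += g * wp[k];
          wp[k] -= lr * g * hp[k];
        }
      }
    }
  } else { // LOSS_NS: target with label 1, sampled negatives with label 0
    const double *hp = h.memptr();
    double *ghp = gh.memptr();
    for (size_t b = 0; b < negs->size() + 1; ++b) {
      int j = (b == 0) ? target : (*negs)[b - 1];
      double label = (b == 0) ? 1.0 : 0.0;
      double *wp = W.colptr(j);
      double dot = 0.0;
      for (int k = 0; k < dim; ++k) dot += wp[k] * hp[k];
      double f = sigmoid(dot);
      loss += -std::log(std::max(label > 0.5 ? f : 1.0 - f, 1e-300));
      double g = f - label;
      if (dW) {
        double *dwp = dW->colptr(j);
        for (int k = 0; k < dim; ++k) {
          ghp[k] += g * wp[k];
          dwp[k] += g * hp[k];
        }
      } else {
        for (int k = 0; k < dim; ++k) {
          ghp[k] += g * wp[k];
          wp[k] -= lr * g * hp[k];
        }
      }
    }
  }
  return loss;
}

static std::vector<double> token_counts(const List &sentences, int vocab) {
  std::vector<double> counts(vocab, 0.0);
  for (int s = 0; s < sentences.size(); ++s) {
    IntegerVector sen = sentences[s];
    for (int t = 0; t < sen.size(); ++t) counts[sen[t]] += 1.0;
  }
  return counts;
}

// unigram^0.75 table for negative sampling
static std::vector<int> build_ns_table(const std::vector<double> &counts,
                                       int table_size = 1 << 17) {
  int V = counts.size();
  double total = 0.0;
  std::vector<double> pw(V);
  for (int i = 0; i < V; ++i) {
    pw[i] = std::pow(counts[i], 0.75);
    total += pw[i];
  }
  std::vector<int> table(table_size);
  int i = 0;
  double cum = pw[0] / total;
  for (int a = 0; a < table_size; ++a) {
    table[a] = i;
    if ((a + 1.0) / table_size > cum && i < V - 1) {
      ++i;
      cum += pw[i] / total;
    }
  }
  return table;
}

// [[Rcpp::export]]
List cbow_train_cpp(List sentences, arma::mat U, int ws, int epochs,
                    double lr, int loss_type, int negatives, double seed) {
  int dim = U.n_rows, vocab = U.n_cols;
  if (vocab < 2) stop("vocabulary must contain at least 2 tokens");
  std::vector<double> counts = token_counts(sentences, vocab);
  HuffmanCode hc;
  std::vector<int> ns_table;
  int n_out = vocab;
  if (loss_type == LOSS_HS) {
    hc = build_huffman(counts);
    n_out = vocab - 1;
  } else if (loss_type == LOSS_NS) {
    ns_table = build_ns_table(counts);
  }
  arma::mat W(dim, n_out, arma::fill::zeros);
  uint64_t rng = (uint64_t)seed * 2862933555777941757ULL + 3037000493ULL;

  // positions with at least one context token, for the lr schedule
  long long total_updates = 0;
  for (int s = 0; s < sentences.size(); ++s) {
    IntegerVector sen = sentences[s];
    if (sen.size() >= 2) total_updates += sen.size();
  }
  total_updates *= (long long)epochs;
  if (total_updates == 0 && epochs > 0) stop("corpus has no trainable context windows");

  long long processed = 0;
  arma::vec h(dim), gh(dim);
  std::vector<int> negs(std::max(negatives, 0));
  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < sentences.size(); ++s) {
      IntegerVector sen = sentences[s];
      int n = sen.size();
      if (n < 2) continue;
      for (int t = 0; t < n; ++t) {
        double alpha = lr * std::max(1e-4, 1.0 - (double)processed / total_updates);
        ++processed;
        int lo = std::max(0, t - ws), hi = std::min(n - 1, t + ws);
        int nctx = hi - lo + 1 - 1;
        if (nctx <= 0) continue;
        h.zeros();
        for (int c = lo; c <= hi; ++c)
          if (c != t) h += U.col(sen[c]);
        h /= nctx;
        if (loss_type == LOSS_NS) {
          for (int b = 0; b < negatives; ++b) {
            int neg;
            do {
              neg = ns_table[sm64(rng) % ns_table.size()];
            } while (neg == sen[t]);
            negs[b] = neg;
          }
        }
        pair_loss_grad(h, sen[t], loss_type, W, alpha, gh, nullptr,
                       &hc, &negs);
        arma::vec upd = (alpha / nctx) * gh;
        for (int c = lo; c <= hi; ++c)
          if (c != t) U.col(sen[c]) -= upd;
      }
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["input"] = U, _["output"] = W);
}

// Corpus loss and analytic gradients at fixed parameters, through the same
// per-pair routine the trainer uses; supports softmax and hierarchical
// softmax (both deterministic). Used by finite-difference tests.
// [[Rcpp::export]]
List cbow_loss_grad_cpp(List sentences, arma::mat U, arma::mat W, int ws,
                        int loss_type) {
  if (loss_type == LOSS_NS)
    stop("loss/grad evaluation supports softmax and hs only");
  int dim = U.n_rows, vocab = U.n_cols;
  HuffmanCode hc;
  if (loss_type == LOSS_HS) hc = build_huffman(token_counts(sentences, vocab));
  arma::mat dU(dim, vocab, arma::fill::zeros);
  arma::mat dW(arma::size(W), arma::fill::zeros);
  arma::vec h(dim), gh(dim);
  double loss = 0.0;
  for (int s = 0; s < sentences.size(); ++s) {
    IntegerVector sen = sentences[s];
    int n = sen.size();
    if (n < 2) continue;
    for (int t = 0; t < n; ++t) {
      int lo = std::max(0, t - ws), hi = std::min(n - 1, t + ws);
      int nctx = hi - lo + 1 - 1;
      if (nctx <= 0) continue;
      h.zeros();
      for (int c = lo; c <= hi; ++c)
        if (c != t) h += U.col(sen[c]);
      h /= nctx;
      loss += pair_loss_grad(h, sen[t], loss_type, W, 0.0, gh, &dW, &hc,
                             nullptr);
      for (int c = lo; c <= hi; ++c)
        if (c != t) dU.col(sen[c]) += gh / nctx;
    }
  }
  return List::create(_["loss"] = loss, _["dU"] = dU, _["dW"] = dW);
}
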