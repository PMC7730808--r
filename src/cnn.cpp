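// 1-D convolutional network for fixed-length sequence feature vectors:
// input (f x 1) -> conv(k=3, same pad, m filters, ReLU) -> maxpool(2)
// -> conv(k=3, same pad, m filters, ReLU) -> maxpool(2) -> dense(ReLU)
// -> dense(ReLU) -> softmax(2). Dropout between layers; Adadelta updates;
// deterministic under a fixed seed (single worker).
//
// Activation matrices use rows = sample*length + position, cols = channels,
// so convolutions become im2col + GEMM over the whole mini-batch.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline uint64_t sm64c(uint64_t &state) {
  uint64_t z = (state += 0x9e3779b97f4a7c15ULL);
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}
static inline double unifc(uint64_t &state) {
  return (sm64c(state) >> 11) * (1.0 / 9007199254740992.0);
}

struct Adadelta {
  arma::mat eg2, ed2;
  double rho, eps;
  void init(const arma::mat &p, double rho_, double eps_) {
    eg2.zeros(arma::size(p));
    ed2.zeros(arma::size(p));
    rho = rho_; eps = eps_;
  }
  void step(arma::mat &p, const arma::mat &g) {
    eg2 = rho * eg2 + (1.0 - rho) * (g % g);
    arma::mat d = -(arma::sqrt(ed2 + eps) / arma::sqrt(eg2 + eps)) % g;
    ed2 = rho * ed2 + (1.0 - rho) * (d % d);
    p += d;
  }
};

static arma::mat glorot(int r, int c, uint64_t &rng) {
  double lim = std::sqrt(6.0 / (r + c));
  arma::mat m(r, c);
  for (arma::uword j = 0; j < m.n_cols; ++j)
    for (arma::uword i = 0; i < m.n_rows; ++i)
      m(i, j) = (2.0 * unifc(rng) - 1.0) * lim;
  return m;
}

// same-padded kernel-3 im2col: A is (B*len x ch); out (B*len x 3*ch)
static arma::mat im2col3(const arma::mat &A, int B, int len) {
  int ch = A.n_cols;
  arma::mat out(A.n_rows, 3 * ch, arma::fill::zeros);
  for (int kk = 0; kk < 3; ++kk) {
    int off = kk - 1;
    int lo = std::max(0, -off), hi = len - 1 - std::max(0, off);
    if (lo > hi) continue;
    for (int s = 0; s < B; ++s) {
      out.submat(s * len + lo, kk * ch, s * len + hi, kk * ch + ch - 1) =
        A.rows(s * len + lo + off, s * len + hi + off);
    }
  }
  return out;
}

static arma::mat col2im3(const arma::mat &dcol, int B, int len) {
  int ch = dcol.n_cols / 3;
  arma::mat dA(dcol.n_rows, ch, arma::fill::zeros);
  for (int kk = 0; kk < 3; ++kk) {
    int off = kk - 1;
    int lo = std::max(0, -off), hi = len - 1 - std::max(0, off);
    if (lo > hi) continue;
    for (int s = 0; s < B; ++s) {
      dA.rows(s * len + lo + off, s * len + hi + off) +=
        dcol.submat(s * len + lo, kk * ch, s * len + hi, kk * ch + ch - 1);
    }
  }
  return dA;
}

// max-pool size 2 with clipped final window (so length 1 inputs survive);
// plen = ceil(len / 2); records source-row indices for backprop
static arma::mat maxpool2(const arma::mat &A, int B, int len,
                          arma::umat &argmax) {
  int plen = (len + 1) / 2, ch = A.n_cols;
  arma::mat out(B * plen, ch);
  argmax.set_size(B * plen, ch);
  for (int s = 0; s < B; ++s) {
    for (int t = 0; t < plen; ++t) {
      int a = s * len + 2 * t;
      int b = std::min(s * len + 2 * t + 1, s * len + len - 1);
      for (int c = 0; c < ch; ++c) {
        if (A(a, c) >= A(b, c)) {
          out(s * plen + t, c) = A(a, c);
          argmax(s * plen + t, c) = a;
        } else {
          out(s * plen + t, c) = A(b, c);
          argmax(s * plen + t, c) = b;
        }
      }
    }
  }
  return out;
}

static arma::mat unpool2(const arma::mat &dP, const arma::umat &argmax,
                         int rows_in) {
  arma::mat dA(rows_in, dP.n_cols, arma::fill::zeros);
  for (arma::uword c = 0; c < dP.n_cols; ++c)
    for (arma::uword r = 0; r < dP.n_rows; ++r)
      dA(argmax(r, c), c) += dP(r, c);
  return dA;
}

// rows = sample*len + pos, cols = ch  ->  (B x len*ch), col index ch*len+pos
static arma::mat flatten_rows(const arma::mat &A, int B, int len) {
  int ch = A.n_cols;
  arma::mat F(B, len * ch);
  for (int s = 0; s < B; ++s)
    for (int c = 0; c < ch; ++c)
      for (int t = 0; t < len; ++t)
        F(s, c * len + t) = A(s * len + t, c);
  return F;
}

static arma::mat unflatten_rows(const arma::mat &F, int len, int ch) {
  int B = F.n_rows;
  arma::mat A(B * len, ch);
  for (int s = 0; s < B; ++s)
    for (int c = 0; c < ch; ++c)
      for (int t = 0; t < len; ++t)
        A(s * len + t, c) = F(s, c * len + t);
  return A;
}

static void dropout_mask(arma::mat &A, double p, uint64_t &rng) {
  if (p <= 0) return;
  double scale = 1.0 / (1.0 - p);
  for (arma::uword j = 0; j < A.n_cols; ++j)
    for (arma::uword i = 0; i < A.n_rows; ++i)
      A(i, j) = (unifc(rng) < p) ? 0.0 : A(i, j) * scale;
}

struct CnnParams {
  arma::mat Wc1, Wc2, Wd1, Wd2, Wo;
  arma::rowvec b1, b2, bd1, bd2, bo;
  int d, m, d1, d2;
};

struct CnnCache {
  arma::mat col1, z1, p1, col2, z2, p2, f, h1, h2, probs;
  arma::umat am1, am2;
};

// forward pass; when training, applies dropout after each pool/dense block
static arma::mat cnn_forward(const CnnParams &P, const arma::mat &X,
                             CnnCache &C, bool train, double drop,
                             uint64_t &rng) {
  int B = X.n_rows;
  arma::mat A = arma::vectorise(X.t());          // (B*d) x 1, one channel
  C.col1 = im2col3(A, B, P.d);
  C.z1 = C.col1 * P.Wc1;
  C.z1.each_row() += P.b1;
  C.z1 = arma::clamp(C.z1, 0.0, arma::datum::inf);
  C.p1 = maxpool2(C.z1, B, P.d, C.am1);
  if (train) dropout_mask(C.p1, drop, rng);
  C.col2 = im2col3(C.p1, B, P.d1);
  C.z2 = C.col2 * P.Wc2;
  C.z2.each_row() += P.b2;
  C.z2 = arma::clamp(C.z2, 0.0, arma::datum::inf);
  C.p2 = maxpool2(C.z2, B, P.d1, C.am2);
  if (train) dropout_mask(C.p2, drop, rng);
  C.f = flatten_rows(C.p2, B, P.d2);
  C.h1 = C.f * P.Wd1;
  C.h1.each_row() += P.bd1;
  C.h1 = arma::clamp(C.h1, 0.0, arma::datum::inf);
  if (train) dropout_mask(C.h1, drop, rng);
  C.h2 = C.h1 * P.Wd2;
  C.h2.each_row() += P.bd2;
  C.h2 = arma::clamp(C.h2, 0.0, arma::datum::inf);
  if (train) dropout_mask(C.h2, drop, rng);
  arma::mat logits = C.h2 * P.Wo;
  logits.each_row() += P.bo;
  arma::vec mx = arma::max(logits, 1);
  logits.each_col() -= mx;
  arma::mat e = arma::exp(logits);
  C.probs = e.each_col() / arma::sum(e, 1);
  return C.probs;
}

// [[Rcpp::export]]
List cnn_train_cpp(arma::mat X, arma::ivec y, int n_filters, int epochs,
                   int batch, double dropout, double rho, double eps,
                   int dense1, int dense2, double seed) {
  int n = X.n_rows, d = X.n_cols;
  if (d < 1) stop("empty feature matrix");
  uint64_t rng = (uint64_t)seed * 6364136223846793005ULL + 1442695040888963407ULL;
  CnnParams P;
  P.d = d; P.m = n_filters;
  P.d1 = (d + 1) / 2; P.d2 = (P.d1 + 1) / 2;
  P.Wc1 = glorot(3, n_filters, rng);             P.b1.zeros(n_filters);
  P.Wc2 = glorot(3 * n_filters, n_filters, rng); P.b2.zeros(n_filters);
  P.Wd1 = glorot(P.d2 * n_filters, dense1, rng); P.bd1.zeros(dense1);
  P.Wd2 = glorot(dense1, dense2, rng);           P.bd2.zeros(dense2);
  P.Wo = glorot(dense2, 2, rng);                 P.bo.zeros(2);

  Adadelta oWc1, oWc2, oWd1, oWd2, oWo, ob1, ob2, obd1, obd2, obo;
  oWc1.init(P.Wc1, rho, eps); oWc2.init(P.Wc2, rho, eps);
  oWd1.init(P.Wd1, rho, eps); oWd2.init(P.Wd2, rho, eps);
  oWo.init(P.Wo, rho, eps);
  arma::mat b1m(P.b1), b2m(P.b2), bd1m(P.bd1), bd2m(P.bd2), bom(P.bo);
  ob1.init(b1m, rho, eps); ob2.init(b2m, rho, eps);
  obd1.init(bd1m, rho, eps); obd2.init(bd2m, rho, eps);
  obo.init(bom, rho, eps);

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  arma::vec epoch_loss(epochs, arma::fill::zeros);
  CnnCache C;

  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates shuffle with the package RNG
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(sm64c(rng) % (uint64_t)(i + 1));
      std::swap(order[i], order[j]);
    }
    double tot = 0.0;
    int nb = 0;
    for (int start = 0; start < n; start += batch) {
      int B = std::min(batch, n - start);
      arma::mat Xb(B, d);
      arma::ivec yb(B);
      for (int i = 0; i < B; ++i) {
        Xb.row(i) = X.row(order[start + i]);
        yb(i) = y(order[start + i]);
      }
      arma::mat probs = cnn_forward(P, Xb, C, true, dropout, rng);
      double loss = 0.0;
      arma::mat dlogits = probs;                 // softmax + CE gradient
      for (int i = 0; i < B; ++i) {
        loss += -std::log(std::max(probs(i, yb(i)), 1e-300));
        dlogits(i, yb(i)) -= 1.0;
      }
      dlogits /= B;
      tot += loss / B;
      ++nb;

      arma::mat dWo = C.h2.t() * dlogits;
      arma::rowvec dbo = arma::sum(dlogits, 0);
      arma::mat dh2 = dlogits * P.Wo.t();
      dh2 %= arma::conv_to<arma::mat>::from(C.h2 > 0);
      arma::mat dWd2 = C.h1.t() * dh2;
      arma::rowvec dbd2 = arma::sum(dh2, 0);
      arma::mat dh1 = dh2 * P.Wd2.t();
      dh1 %= arma::conv_to<arma::mat>::from(C.h1 > 0);
      arma::mat dWd1 = C.f.t() * dh1;
      arma::rowvec dbd1 = arma::sum(dh1, 0);
      arma::mat df = dh1 * P.Wd1.t();
      arma::mat dp2 = unflatten_rows(df, P.d2, n_filters);
      arma::mat dz2 = unpool2(dp2, C.am2, C.z2.n_rows);
      dz2 %= arma::conv_to<arma::mat>::from(C.z2 > 0);
      arma::mat dWc2 = C.col2.t() * dz2;
      arma::rowvec db2 = arma::sum(dz2, 0);
      arma::mat dcol2 = dz2 * P.Wc2.t();
      arma::mat dp1 = col2im3(dcol2, B, P.d1);
      arma::mat dz1 = unpool2(dp1, C.am1, C.z1.n_rows);
      dz1 %= arma::conv_to<arma::mat>::from(C.z1 > 0);
      arma::mat dWc1 = C.col1.t() * dz1;
      arma::rowvec db1 = arma::sum(dz1, 0);

      oWo.step(P.Wo, dWo); oWd2.step(P.Wd2, dWd2); oWd1.step(P.Wd1, dWd1);
      oWc2.step(P.Wc2, dWc2); oWc1.step(P.Wc1, dWc1);
      arma::mat t1(dbo), t2(dbd2), t3(dbd1), t4(db2), t5(db1);
      obo.step(bom, t1); obd2.step(bd2m, t2); obd1.step(bd1m, t3);
      ob2.step(b2m, t4); ob1.step(b1m, t5);
      P.bo = bom.row(0); P.bd2 = bd2m.row(0); P.bd1 = bd1m.row(0);
      P.b2 = b2m.row(0); P.b1 = b1m.row(0);
    }
    epoch_loss(ep) = tot / std::max(nb, 1);
    Rcpp::checkUserInterrupt();
  }
  return List::create(
    _["Wc1"] = P.Wc1, _["b1"] = P.b1, _["Wc2"] = P.Wc2, _["b2"] = P.b2,
    _["Wd1"] = P.Wd1, _["bd1"] = P.bd1, _["Wd2"] = P.Wd2, _["bd2"] = P.bd2,
    _["Wo"] = P.Wo, _["bo"] = P.bo, _["epoch_loss"] = epoch_loss,
    _["d"] = d, _["m"] = n_filters, _["d1"] = P.d1, _["d2"] = P.d2);
}

// [[Rcpp::export]]
arma::mat cnn_predict_cpp(List fit, arma::mat X) {
  CnnParams P;
  P.Wc1 = as<arma::mat>(fit["Wc1"]); P.b1 = as<arma::rowvec>(fit["b1"]);
  P.Wc2 = as<arma::mat>(fit["Wc2"]); P.b2 = as<arma::rowvec>(fit["b2"]);
  P.Wd1 = as<arma::mat>(fit["Wd1"]); P.bd1 = as<arma::rowvec>(fit["bd1"]);
  P.Wd2 = as<arma::mat>(fit["Wd2"]); P.bd2 = as<arma::rowvec>(fit["bd2"]);
  P.Wo = as<arma::mat>(fit["Wo"]); P.bo = as<arma::rowvec>(fit["bo"]);
  P.d = as<int>(fit["d"]); P.m = as<int>(fit["m"]);
  P.d1 = as<int>(fit["d1"]); P.d2 = as<int>(fit["d2"]);
  if ((int)X.n_cols != P.d)
    stop("feature width %d does not match training width %d",
         (int)X.n_cols, P.d);
  CnnCache C;
  uint64_t rng = 0;
  return cnn_forward(P, X, C, false, 0.0, rng);
}
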