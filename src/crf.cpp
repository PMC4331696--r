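// Linear-chain CRF core over the label set {O, B, I} (1, 2, 3 on the R
// side). State features are sparse per-token feature-index vectors; the
// nine transition weights sit after the state block. Transitions into I
// from O and sequence-initial I are structurally disallowed, so every
// decoded sequence is valid BIO by construction.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

static const int K = 3;            // O, B, I
static const double NEG_INF = -std::numeric_limits<double>::infinity();

// transition prev -> cur allowed? cur == I (index 2) needs prev B or I
static inline bool allowed(int prev, int cur) {
  return !(cur == 2 && prev == 0);
}
static inline bool allowed_start(int cur) { return cur != 2; }

static inline double logsumexp3(const double* v) {
  double m = v[0];
  if (v[1] > m) m = v[1];
  if (v[2] > m) m = v[2];
  if (m == NEG_INF) return NEG_INF;
  double s = 0.0;
  for (int k = 0; k < K; ++k) s += std::exp(v[k] - m);
  return m + std::log(s);
}

// per-token state scores: psi[t][k] = sum over features f of w[(f-1)*3 + k]
static void state_scores(const NumericVector& w, const List& sent,
                         std::vector<double>& psi) {
  int T = sent.size();
  psi.assign((size_t)T * K, 0.0);
  for (int t = 0; t < T; ++t) {
    IntegerVector fs = sent[t];
    for (int j = 0; j < fs.size(); ++j) {
      int f = fs[j] - 1;
      for (int k = 0; k < K; ++k)
        psi[(size_t)t * K + k] += w[(size_t)f * K + k];
    }
  }
}

static inline double trans_w(const NumericVector& w, int nfeat,
                             int prev, int cur) {
  return w[(size_t)nfeat * K + prev * K + cur];
}

// forward/backward in log space; returns logZ
static double forward_backward(const NumericVector& w, int nfeat,
                               const std::vector<double>& psi, int T,
                               std::vector<double>& alpha,
                               std::vector<double>& beta) {
  alpha.assign((size_t)T * K, NEG_INF);
  beta.assign((size_t)T * K, NEG_INF);
  for (int k = 0; k < K; ++k)
    if (allowed_start(k)) alpha[k] = psi[k];
  double buf[K];
  for (int t = 1; t < T; ++t)
    for (int k = 0; k < K; ++k) {
      for (int j = 0; j < K; ++j)
        buf[j] = (allowed(j, k) && alpha[(size_t)(t - 1) * K + j] != NEG_INF)
                   ? alpha[(size_t)(t - 1) * K + j] + trans_w(w, nfeat, j, k)
                   : NEG_INF;
      double lse = logsumexp3(buf);
      alpha[(size_t)t * K + k] =
          (lse == NEG_INF) ? NEG_INF : lse + psi[(size_t)t * K + k];
    }
  for (int k = 0; k < K; ++k) beta[(size_t)(T - 1) * K + k] = 0.0;
  for (int t = T - 2; t >= 0; --t)
    for (int j = 0; j < K; ++j) {
      for (int k = 0; k < K; ++k)
        buf[k] = allowed(j, k)
                   ? trans_w(w, nfeat, j, k) + psi[(size_t)(t + 1) * K + k] +
                     beta[(size_t)(t + 1) * K + k]
                   : NEG_INF;
      beta[(size_t)t * K + j] = logsumexp3(buf);
    }
  double last[K];
  for (int k = 0; k < K; ++k) last[k] = alpha[(size_t)(T - 1) * K + k];
  return logsumexp3(last);
}

// [[Rcpp::export(name = ".crf_nll_grad")]]
List crf_nll_grad(NumericVector w, List sentences, List labels, int nfeat) {
  NumericVector grad(w.size());
  double nll = 0.0;
  std::vector<double> psi, alpha, beta;
  for (int s = 0; s < sentences.size(); ++s) {
    List sent = sentences[s];
    IntegerVector y = labels[s];
    int T = sent.size();
    if (T == 0) continue;
    state_scores(w, sent, psi);
    double logZ = forward_backward(w, nfeat, psi, T, alpha, beta);
    // gold path score
    double gold = psi[(size_t)0 * K + (y[0] - 1)];
    for (int t = 1; t < T; ++t)
      gold += trans_w(w, nfeat, y[t - 1] - 1, y[t] - 1) +
              psi[(size_t)t * K + (y[t] - 1)];
    nll += logZ - gold;
    // node marginals -> state-feature gradient
    for (int t = 0; t < T; ++t) {
      double p[K];
      for (int k = 0; k < K; ++k) {
        double a = alpha[(size_t)t * K + k];
        p[k] = (a == NEG_INF) ? 0.0
                              : std::exp(a + beta[(size_t)t * K + k] - logZ);
      }
      IntegerVector fs = sent[t];
      for (int j = 0; j < fs.size(); ++j) {
        int f = fs[j] - 1;
        for (int k = 0; k < K; ++k)
          grad[(size_t)f * K + k] += p[k];
        grad[(size_t)f * K + (y[t] - 1)] -= 1.0;
      }
    }
    // edge marginals -> transition gradient
    for (int t = 1; t < T; ++t) {
      for (int j = 0; j < K; ++j) {
        double a = alpha[(size_t)(t - 1) * K + j];
        if (a == NEG_INF) continue;
        for (int k = 0; k < K; ++k) {
          if (!allowed(j, k)) continue;
          double lp = a + trans_w(w, nfeat, j, k) + psi[(size_t)t * K + k] +
                      beta[(size_t)t * K + k] - logZ;
          grad[(size_t)nfeat * K + j * K + k] += std::exp(lp);
        }
      }
      grad[(size_t)nfeat * K + (y[t - 1] - 1) * K + (y[t] - 1)] -= 1.0;
    }
  }
  return List::create(Named("nll") = nll, Named("grad") = grad);
}

// [[Rcpp::export(name = ".crf_viterbi")]]
IntegerVector crf_viterbi(NumericVector w, List sent, int nfeat) {
  int T = sent.size();
  IntegerVector out(T);
  if (T == 0) return out;
  std::vector<double> psi;
  state_scores(w, sent, psi);
  std::vector<double> delta((size_t)T * K, NEG_INF);
  std::vector<int> back((size_t)T * K, -1);
  for (int k = 0; k < K; ++k)
    if (allowed_start(k)) delta[k] = psi[k];
  for (int t = 1; t < T; ++t)
    for (int k = 0; k < K; ++k) {
      double best = NEG_INF;
      int arg = -1;
      for (int j = 0; j < K; ++j) {
        if (!allowed(j, k) || delta[(size_t)(t - 1) * K + j] == NEG_INF)
          continue;
        double v = delta[(size_t)(t - 1) * K + j] + trans_w(w, nfeat, j, k);
        if (v > best) { best = v; arg = j; }
      }
      if (arg >= 0) {
        delta[(size_t)t * K + k] = best + psi[(size_t)t * K + k];
        back[(size_t)t * K + k] = arg;
      }
    }
  int cur = 0;
  double best = NEG_INF;
  for (int k = 0; k < K; ++k)
    if (delta[(size_t)(T - 1) * K + k] > best) {
      best = delta[(size_t)(T - 1) * K + k];
      cur = k;
    }
  for (int t = T - 1; t >= 0; --t) {
    out[t] = cur + 1;
    cur = back[(size_t)t * K + cur];
  }
  return out;
}

// [[Rcpp::export(name = ".crf_marginals")]]
NumericMatrix crf_marginals(NumericVector w, List sent, int nfeat) {
  int T = sent.size();
  NumericMatrix out(T, K);
  if (T == 0) return out;
  std::vector<double> psi, alpha, beta;
  state_scores(w, sent, psi);
  double logZ = forward_backward(w, nfeat, psi, T, alpha, beta);
  for (int t = 0; t < T; ++t)
    for (int k = 0; k < K; ++k) {
      double a = alpha[(size_t)t * K + k];
      out(t, k) = (a == NEG_INF)
                    ? 0.0
                    : std::exp(a + beta[(size_t)t * K + k] - logZ);
    }
  return out;
}
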