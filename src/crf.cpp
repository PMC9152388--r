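#include <Rcpp.h>
using namespace Rcpp;

// Linear-chain CRF inference over labels 1..L with two augmented boundary
// states in the transition matrix W ((L+2) x (L+2)): START = L+1, STOP = L+2
// (1-based). P is the n x L emission score matrix.

static inline double logsumexp(const std::vector<double>& v) {
  double m = v[0];
  for (size_t i = 1; i < v.size(); ++i) if (v[i] > m) m = v[i];
  if (!R_finite(m)) return m;
  double s = 0.0;
  for (size_t i = 0; i < v.size(); ++i) s += std::exp(v[i] - m);
  return m + std::log(s);
}

// forward algorithm: returns log partition and the alpha lattice
// [[Rcpp::export]]
List crf_forward_cpp(NumericMatrix P, NumericMatrix W) {
  int n = P.nrow(), L = P.ncol();
  int START = L, STOP = L + 1; // 0-based rows/cols in W
  NumericMatrix alpha(n, L);
  std::vector<double> tmp(L);
  for (int j = 0; j < L; ++j) alpha(0, j) = W(START, j) + P(0, j);
  for (int t = 1; t < n; ++t) {
    for (int j = 0; j < L; ++j) {
      for (int i = 0; i < L; ++i) tmp[i] = alpha(t - 1, i) + W(i, j);
      alpha(t, j) = logsumexp(tmp) + P(t, j);
    }
  }
  for (int j = 0; j < L; ++j) tmp[j] = alpha(n - 1, j) + W(j, STOP);
  double logZ = logsumexp(tmp);
  return List::create(_["log_partition"] = logZ, _["alpha"] = alpha);
}

// node marginals and expected transition counts (for the NLL gradient)
// [[Rcpp::export]]
List crf_marginals_cpp(NumericMatrix P, NumericMatrix W) {
  int n = P.nrow(), L = P.ncol();
  int START = L, STOP = L + 1;
  NumericMatrix alpha(n, L), beta(n, L);
  std::vector<double> tmp(L);
  for (int j = 0; j < L; ++j) alpha(0, j) = W(START, j) + P(0, j);
  for (int t = 1; t < n; ++t)
    for (int j = 0; j < L; ++j) {
      for (int i = 0; i < L; ++i) tmp[i] = alpha(t - 1, i) + W(i, j);
      alpha(t, j) = logsumexp(tmp) + P(t, j);
    }
  for (int j = 0; j < L; ++j) tmp[j] = alpha(n - 1, j) + W(j, STOP);
  double logZ = logsumexp(tmp);

  for (int j = 0; j < L; ++j) beta(n - 1, j) = W(j, STOP);
  for (int t = n - 2; t >= 0; --t)
    for (int i = 0; i < L; ++i) {
      for (int j = 0; j < L; ++j)
        tmp[j] = W(i, j) + P(t + 1, j) + beta(t + 1, j);
      beta(t, i) = logsumexp(tmp);
    }

  NumericMatrix node(n, L);
  for (int t = 0; t < n; ++t)
    for (int j = 0; j < L; ++j)
      node(t, j) = std::exp(alpha(t, j) + beta(t, j) - logZ);

  NumericMatrix trans(L + 2, L + 2);
  for (int t = 0; t + 1 < n; ++t)
    for (int i = 0; i < L; ++i)
      for (int j = 0; j < L; ++j)
        trans(i, j) += std::exp(alpha(t, i) + W(i, j) + P(t + 1, j) +
                                beta(t + 1, j) - logZ);
  for (int j = 0; j < L; ++j) {
    trans(START, j) = node(0, j);
    trans(j, STOP) = node(n - 1, j);
  }
  return List::create(_["log_partition"] = logZ, _["node"] = node,
                      _["transition"] = trans);
}

// Viterbi decoding; ties broken toward the lowest label index at the latest
// differing position (strict > comparisons keep the first maximizer)
// [[Rcpp::export]]
List crf_viterbi_cpp(NumericMatrix P, NumericMatrix W) {
  int n = P.nrow(), L = P.ncol();
  int START = L, STOP = L + 1;
  NumericMatrix delta(n, L);
  IntegerMatrix back(n, L);
  for (int j = 0; j < L; ++j) delta(0, j) = W(START, j) + P(0, j);
  for (int t = 1; t < n; ++t)
    for (int j = 0; j < L; ++j) {
      double best = delta(t - 1, 0) + W(0, j);
      int arg = 0;
      for (int i = 1; i < L; ++i) {
        double s = delta(t - 1, i) + W(i, j);
        if (s > best) { best = s; arg = i; }
      }
      delta(t, j) = best + P(t, j);
      back(t, j) = arg;
    }
  double best = delta(n - 1, 0) + W(0, STOP);
  int arg = 0;
  for (int j = 1; j < L; ++j) {
    double s = delta(n - 1, j) + W(j, STOP);
    if (s > best) { best = s; arg = j; }
  }
  IntegerVector path(n);
  path[n - 1] = arg;
  for (int t = n - 1; t > 0; --t) path[t - 1] = back(t, path[t]);
  for (int t = 0; t < n; ++t) path[t] += 1; // 1-based labels for R
  return List::create(_["path"] = path, _["score"] = best);
}
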