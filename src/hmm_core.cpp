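#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward over one chain.
// logB: T x K per-frame log emission weights (may be unnormalised, as in
// variational E-steps where exp(E[log p]) is subnormalised);
// logA: K x K log transition weights; logpi: K log initial weights.
// Returns log-normaliser, per-frame responsibilities gamma (T x K) and the
// transition responsibilities xi summed over frame pairs (K x K).
// [[Rcpp::export]]
List fb_core(NumericMatrix logB, NumericMatrix logA, NumericVector logpi) {
  const int T = logB.nrow(), K = logB.ncol();
  NumericMatrix A(K, K);
  NumericVector pi0(K);
  for (int i = 0; i < K; ++i) {
    pi0[i] = std::exp(logpi[i]);
    for (int j = 0; j < K; ++j) A(i, j) = std::exp(logA(i, j));
  }

  NumericMatrix alpha(T, K), beta(T, K), B(T, K);
  NumericVector c(T), bmax(T);
  for (int t = 0; t < T; ++t) {
    double m = logB(t, 0);
    for (int k = 1; k < K; ++k) if (logB(t, k) > m) m = logB(t, k);
    bmax[t] = m;
    for (int k = 0; k < K; ++k) B(t, k) = std::exp(logB(t, k) - m);
  }

  double s = 0.0;
  for (int k = 0; k < K; ++k) { alpha(0, k) = pi0[k] * B(0, k); s += alpha(0, k); }
  if (!(s > 0.0)) stop("forward pass underflow at frame 0");
  c[0] = s;
  for (int k = 0; k < K; ++k) alpha(0, k) /= s;
  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int j = 0; j < K; ++j) {
      double a = 0.0;
      for (int i = 0; i < K; ++i) a += alpha(t - 1, i) * A(i, j);
      a *= B(t, j);
      alpha(t, j) = a;
      s += a;
    }
    if (!(s > 0.0)) stop("forward pass underflow");
    c[t] = s;
    for (int j = 0; j < K; ++j) alpha(t, j) /= s;
  }

  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int i = 0; i < K; ++i) {
      double b = 0.0;
      for (int j = 0; j < K; ++j) b += A(i, j) * B(t + 1, j) * beta(t + 1, j);
      beta(t, i) = b / c[t + 1];
    }
  }

  NumericMatrix gamma(T, K), xi(K, K);
  for (int t = 0; t < T; ++t)
    for (int k = 0; k < K; ++k) gamma(t, k) = alpha(t, k) * beta(t, k);
  for (int t = 1; t < T; ++t)
    for (int i = 0; i < K; ++i)
      for (int j = 0; j < K; ++j)
        xi(i, j) += alpha(t - 1, i) * A(i, j) * B(t, j) * beta(t, j) / c[t];

  double logZ = 0.0;
  for (int t = 0; t < T; ++t) logZ += std::log(c[t]) + bmax[t];

  return List::create(_["logZ"] = logZ, _["gamma"] = gamma, _["xi"] = xi);
}

// Most probable state path; ties broken toward the lower state index.
// [[Rcpp::export]]
IntegerVector viterbi_core(NumericMatrix logB, NumericMatrix logA, NumericVector logpi) {
  const int T = logB.nrow(), K = logB.ncol();
  NumericMatrix d(T, K);
  IntegerMatrix psi(T, K);
  for (int k = 0; k < K; ++k) d(0, k) = logpi[k] + logB(0, k);
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < K; ++j) {
      double best = d(t - 1, 0) + logA(0, j);
      int arg = 0;
      for (int i = 1; i < K; ++i) {
        double v = d(t - 1, i) + logA(i, j);
        if (v > best) { best = v; arg = i; }
      }
      d(t, j) = best + logB(t, j);
      psi(t, j) = arg;
    }
  }
  IntegerVector path(T);
  int arg = 0;
  double best = d(T - 1, 0);
  for (int k = 1; k < K; ++k) if (d(T - 1, k) > best) { best = d(T - 1, k); arg = k; }
  path[T - 1] = arg;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  return path;
}

// Sample a Markov chain path of length n from row-stochastic P given
// pre-drawn uniforms (one per frame); states returned 0-based.
// [[Rcpp::export]]
IntegerVector sim_path_core(NumericMatrix P, NumericVector init, NumericVector u) {
  const int n = u.size(), K = P.ncol();
  IntegerVector path(n);
  double acc = 0.0;
  int s = K - 1;
  for (int k = 0; k < K; ++k) { acc += init[k]; if (u[0] <= acc) { s = k; break; } }
  path[0] = s;
  for (int t = 1; t < n; ++t) {
    acc = 0.0;
    int nxt = K - 1;
    for (int k = 0; k < K; ++k) { acc += P(s, k); if (u[t] <= acc) { nxt = k; break; } }
    s = nxt;
    path[t] = s;
  }
  return path;
}
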