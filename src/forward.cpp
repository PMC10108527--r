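#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Scaled forward recursion for one track of a hidden Markov model.
//
// logdens: T x N log emission densities (rows of zeros where all streams
//   are missing). delta: initial state distribution. gamma: transition
//   probabilities, either a single column-major N x N matrix (homogeneous)
//   or (T-1) stacked matrices where slice t (0-based) governs the
//   transition from time t+1 to t+2.
// [[Rcpp::export]]
double forward_loglik_cpp(const NumericMatrix& logdens,
                          const NumericVector& delta,
                          const NumericVector& gamma,
                          const bool homogeneous) {
  const int T = logdens.nrow(), N = logdens.ncol();
  std::vector<double> phi(N), a(N);
  double ll = 0.0;

  double m = R_NegInf;
  for (int i = 0; i < N; ++i) m = std::max(m, logdens(0, i));
  if (m == R_NegInf) return R_NegInf;
  double s = 0.0;
  for (int i = 0; i < N; ++i) {
    phi[i] = delta[i] * std::exp(logdens(0, i) - m);
    s += phi[i];
  }
  if (!(s > 0.0) || !R_finite(s)) return R_NegInf;
  ll += m + std::log(s);
  for (int i = 0; i < N; ++i) phi[i] /= s;

  for (int t = 1; t < T; ++t) {
    const double* G =
        homogeneous ? &gamma[0] : &gamma[static_cast<size_t>(t - 1) * N * N];
    m = R_NegInf;
    for (int j = 0; j < N; ++j) m = std::max(m, logdens(t, j));
    if (m == R_NegInf) return R_NegInf;
    s = 0.0;
    for (int j = 0; j < N; ++j) {
      double aj = 0.0;
      for (int i = 0; i < N; ++i) aj += phi[i] * G[i + j * N];
      a[j] = aj * std::exp(logdens(t, j) - m);
      s += a[j];
    }
    if (!(s > 0.0) || !R_finite(s)) return R_NegInf;
    ll += m + std::log(s);
    for (int j = 0; j < N; ++j) phi[j] = a[j] / s;
  }
  return ll;
}
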