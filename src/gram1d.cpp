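// Weighted 1-D RBF mean-embedding inner products for the per-gene scan.
// Each donor's gene column is compressed to (unique value, weight) pairs;
// <p_i, p_j> = sum_u sum_v w_iu w_jv exp(-gamma (u - v)^2), identical to
// the n^2 double loop because weights are tie counts divided by n.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export(name = ".gram1d_cpp")]]
NumericMatrix gram1d_cpp(List values, List weights, double gamma) {
  const int N = values.size();
  NumericMatrix G(N, N);
  std::vector<NumericVector> v(N), w(N);
  for (int i = 0; i < N; ++i) {
    v[i] = as<NumericVector>(values[i]);
    w[i] = as<NumericVector>(weights[i]);
  }
  for (int i = 0; i < N; ++i) {
    for (int j = i; j < N; ++j) {
      double s = 0.0;
      const NumericVector &vi = v[i], &wi = w[i], &vj = v[j], &wj = w[j];
      for (int a = 0; a < vi.size(); ++a) {
        double acc = 0.0;
        const double va = vi[a];
        for (int b = 0; b < vj.size(); ++b) {
          const double d = va - vj[b];
          acc += wj[b] * std::exp(-gamma * d * d);
        }
        s += wi[a] * acc;
      }
      G(i, j) = s;
      G(j, i) = s;
    }
  }
  return G;
}
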