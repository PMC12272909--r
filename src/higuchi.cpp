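#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Curve length L_i(j) of the subsampled series X(i), X(i+j), ..., with the
// standard normalization (N-1) / (floor((N-i)/j) * j). i is 1-based.
// [[Rcpp::export]]
double higuchi_curve_length_cpp(NumericVector x, int i, int j) {
  const int N = x.size();
  const int M = (N - i) / j; // number of successive differences
  if (M < 1) stop("degenerate: fewer than 2 points in the subsampled series");
  double s = 0.0;
  for (int m = 1; m <= M; ++m) {
    s += std::fabs(x[i - 1 + m * j] - x[i - 1 + (m - 1) * j]);
  }
  return s * (double)(N - 1) / ((double)M * (double)j);
}

// Mean curve length per interval j = 1..kmax: L(j) = (1/j) * mean_i L_i(j),
// the curvilinear-time correction 1/j applied at the averaging stage.
// [[Rcpp::export]]
NumericVector higuchi_mean_lengths_cpp(NumericVector x, int kmax) {
  const int N = x.size();
  NumericVector L(kmax);
  for (int j = 1; j <= kmax; ++j) {
    double acc = 0.0;
    for (int i = 1; i <= j; ++i) {
      const int M = (N - i) / j;
      double s = 0.0;
      for (int m = 1; m <= M; ++m) {
        s += std::fabs(x[i - 1 + m * j] - x[i - 1 + (m - 1) * j]);
      }
      acc += s * (double)(N - 1) / ((double)M * (double)j);
    }
    L[j - 1] = acc / ((double)j * (double)j);
  }
  return L;
}
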