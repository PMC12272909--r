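#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// One IIR pass in direct form II transposed with explicit initial state z:
// y[i] = b0 x[i] + z0;  z_k <- b_{k+1} x[i] + z_{k+1} - a_{k+1} y[i].
// b and a are normalized to a[0] = 1 and zero-padded to equal length m+1.
static void df2t_filter(const std::vector<double>& b, const std::vector<double>& a,
                        const double* x, double* y, int n, std::vector<double> z) {
  const int m = (int)b.size() - 1;
  for (int i = 0; i < n; ++i) {
    const double yi = b[0] * x[i] + z[0];
    for (int k = 0; k < m - 1; ++k) {
      z[k] = b[k + 1] * x[i] + z[k + 1] - a[k + 1] * yi;
    }
    z[m - 1] = b[m] * x[i] - a[m] * yi;
    y[i] = yi;
  }
}

struct ZeroPhaseFilter {
  std::vector<double> b, a, zi;
  int m;       // filter order (state length)
  int padlen;  // reflection padding per side

  ZeroPhaseFilter(NumericVector b_, NumericVector a_, int padlen_) {
    const int nf = std::max(b_.size(), a_.size());
    m = nf - 1;
    padlen = padlen_;
    b.assign(nf, 0.0);
    a.assign(nf, 0.0);
    for (int i = 0; i < b_.size(); ++i) b[i] = b_[i];
    for (int i = 0; i < a_.size(); ++i) a[i] = a_[i];
    for (int i = nf - 1; i >= 0; --i) { b[i] /= a[0]; }
    for (int i = nf - 1; i >= 0; --i) { a[i] /= a[0]; }
    // steady-state initial conditions of the unit step response:
    // (I - A^T) zi = B with A the companion matrix of a,
    // B_k = b[k+1] - a[k+1] b[0]
    std::vector<double> M(m * m, 0.0), B(m);
    for (int k = 0; k < m; ++k) {
      B[k] = b[k + 1] - a[k + 1] * b[0];
      M[k * m + 0] += a[k + 1];          // companion first column, transposed
      if (k > 0) M[(k - 1) * m + k] -= 1.0;
      M[k * m + k] += 1.0;
    }
    // Gaussian elimination with partial pivoting (m <= 8 in practice)
    zi.assign(m, 0.0);
    for (int col = 0; col < m; ++col) {
      int piv = col;
      for (int r = col + 1; r < m; ++r) {
        if (std::fabs(M[r * m + col]) > std::fabs(M[piv * m + col])) piv = r;
      }
      if (piv != col) {
        for (int c = 0; c < m; ++c) std::swap(M[col * m + c], M[piv * m + c]);
        std::swap(B[col], B[piv]);
      }
      const double d = M[col * m + col];
      for (int r = col + 1; r < m; ++r) {
        const double f = M[r * m + col] / d;
        for (int c = col; c < m; ++c) M[r * m + c] -= f * M[col * m + c];
        B[r] -= f * B[col];
      }
    }
    for (int r = m - 1; r >= 0; --r) {
      double s = B[r];
      for (int c = r + 1; c < m; ++c) s -= M[r * m + c] * zi[c];
      zi[r] = s / M[r * m + r];
    }
  }

  // Forward-backward filtering with odd-reflection padding on both ends and
  // initial conditions matched to the first padded sample of each pass.
  void apply(const double* x, double* out, int n,
             std::vector<double>& ext, std::vector<double>& y1,
             std::vector<double>& y2) const {
    if (n <= padlen) stop("trial too short: %d samples for a filter needing > %d",
                          n, padlen);
    const int ne = n + 2 * padlen;
    ext.resize(ne); y1.resize(ne); y2.resize(ne);
    for (int i = 0; i < padlen; ++i) ext[i] = 2.0 * x[0] - x[padlen - i];
    for (int i = 0; i < n; ++i) ext[padlen + i] = x[i];
    for (int i = 0; i < padlen; ++i) ext[padlen + n + i] = 2.0 * x[n - 1] - x[n - 2 - i];
    std::vector<double> z(m);
    for (int k = 0; k < m; ++k) z[k] = zi[k] * ext[0];
    df2t_filter(b, a, ext.data(), y1.data(), ne, z);
    std::reverse(y1.begin(), y1.end());
    for (int k = 0; k < m; ++k) z[k] = zi[k] * y1[0];
    df2t_filter(b, a, y1.data(), y2.data(), ne, z);
    std::reverse(y2.begin(), y2.end());
    for (int i = 0; i < n; ++i) out[i] = y2[padlen + i];
  }
};

// Zero-phase (forward-backward) IIR filtering of one series.
// [[Rcpp::export]]
NumericVector filtfilt_cpp(NumericVector b, NumericVector a, NumericVector x,
                           int padlen) {
  ZeroPhaseFilter f(b, a, padlen);
  NumericVector out(x.size());
  std::vector<double> ext, y1, y2;
  f.apply(REAL(x), REAL(out), x.size(), ext, y1, y2);
  return out;
}

// Zero-phase filtering of every (trial, channel) series of a
// trials x channels x samples array along the sample axis.
// [[Rcpp::export]]
NumericVector filtfilt_array_cpp(NumericVector b, NumericVector a, NumericVector arr,
                                 int padlen) {
  IntegerVector dims = arr.attr("dim");
  if (dims.size() != 3) stop("expected a 3-d array");
  const int nt = dims[0], nc = dims[1], ns = dims[2];
  ZeroPhaseFilter f(b, a, padlen);
  NumericVector out(clone(arr));
  const R_xlen_t stride = (R_xlen_t)nt * nc;
  std::vector<double> xs(ns), ys(ns), ext, y1, y2;
  for (int tr = 0; tr < nt; ++tr) {
    for (int ch = 0; ch < nc; ++ch) {
      const R_xlen_t base = tr + (R_xlen_t)nt * ch;
      for (int s = 0; s < ns; ++s) xs[s] = arr[base + stride * s];
      f.apply(xs.data(), ys.data(), ns, ext, y1, y2);
      for (int s = 0; s < ns; ++s) out[base + stride * s] = ys[s];
    }
  }
  out.attr("dim") = dims;
  return out;
}

// Quantile type 7 (the R default) on a sorted copy.
static double quantile7(std::vector<double>& s, double p) {
  const int n = s.size();
  double h = (n - 1) * p;
  int lo = (int)std::floor(h);
  int hi = std::min(lo + 1, n - 1);
  return s[lo] + (h - lo) * (s[hi] - s[lo]);
}

// Differential entropy of one sample window via the equal-width histogram
// with the automatic bin rule (max of Sturges and Freedman-Diaconis),
// matching the R-level estimator bin for bin.
// [[Rcpp::export]]
double de_entropy_auto_cpp(NumericVector x) {
  const int n = x.size();
  if (n < 2) stop("need at least 2 samples");
  double lo = x[0], hi = x[0];
  for (int i = 1; i < n; ++i) {
    if (x[i] < lo) lo = x[i];
    if (x[i] > hi) hi = x[i];
  }
  if (lo == hi) stop("degenerate distribution: all samples identical (point mass)");
  // Sturges: ceil(log2(n)) + 1; Freedman-Diaconis: ceil(range / (2 IQR n^-1/3))
  int sturges = (int)std::ceil(std::log2((double)n)) + 1;
  std::vector<double> s(x.begin(), x.end());
  std::sort(s.begin(), s.end());
  double iqr = quantile7(s, 0.75) - quantile7(s, 0.25);
  double h = 2.0 * iqr * std::pow((double)n, -1.0 / 3.0);
  int fd = (h > 0) ? (int)std::ceil((hi - lo) / h) : 1;
  int bins = std::max(std::max(sturges, fd), 1);
  // edges as seq(lo, hi, length.out = bins + 1) computes them
  std::vector<double> edges(bins + 1);
  double by = (hi - lo) / bins;
  for (int i = 0; i <= bins; ++i) edges[i] = lo + i * by;
  edges[bins] = hi;
  std::vector<int> counts(bins, 0);
  for (int i = 0; i < n; ++i) {
    // findInterval with rightmost.closed: last bin closed on both sides
    int idx = (int)(std::upper_bound(edges.begin(), edges.end(), x[i]) - edges.begin()) - 1;
    if (idx >= bins) idx = bins - 1;
    if (idx < 0) idx = 0;
    ++counts[idx];
  }
  double ent = 0.0;
  for (int i = 0; i < bins; ++i) {
    if (counts[i] == 0) continue;
    double w = edges[i + 1] - edges[i];
    double d = counts[i] / (n * w);
    ent -= d * std::log(d) * w;
  }
  return ent;
}
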