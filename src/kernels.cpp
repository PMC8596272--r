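#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Cascade of biquads in direct form II transposed (all sections fused into
// one pass).  sos: n_sections x 6 (b0 b1 b2 1 a1 a2); zi: n_sections x 2
// initial state (already scaled by the caller).
// [[Rcpp::export(name = ".sosfilt_cpp")]]
NumericVector sosfilt_cpp(NumericVector x, NumericMatrix sos, NumericMatrix zi) {
  const int n = x.size(), ns = sos.nrow();
  NumericVector y(n);
  std::vector<double> z1(ns), z2(ns);
  for (int s = 0; s < ns; ++s) { z1[s] = zi(s, 0); z2[s] = zi(s, 1); }
  for (int i = 0; i < n; ++i) {
    double v = x[i];
    for (int s = 0; s < ns; ++s) {
      const double yi = sos(s, 0) * v + z1[s];
      z1[s] = sos(s, 1) * v - sos(s, 4) * yi + z2[s];
      z2[s] = sos(s, 2) * v - sos(s, 5) * yi;
      v = yi;
    }
    y[i] = v;
  }
  return y;
}

// Higuchi mean curve lengths L(k), k = 1..k_max, original normalization:
// L_m(k) = (1/k) * [ sum_{i=1}^{M_m} |x(m+ik) - x(m+(i-1)k)| ] * (N-1)/(M_m*k),
// M_m = floor((N-m)/k); L(k) = mean over m = 1..k.
//
// The lag-k differences are accumulated in one sequential sweep (every pair
// (j, j+k) belongs to the sub-series with offset m = ((j-1) mod k) + 1),
// which keeps both read streams contiguous.
static void curve_lengths_into(const double *p, int n, int k_max, double *L) {
  std::vector<double> srun;
  for (int k = 1; k <= k_max; ++k) {
    srun.assign(k, 0.0);
    int r = 0;
    for (int j = 0; j + k < n; ++j) {
      srun[r] += std::fabs(p[j + k] - p[j]);
      if (++r == k) r = 0;
    }
    double acc = 0.0;
    bool ok = true;
    for (int m = 1; m <= k; ++m) {
      const int M = (n - m) / k;
      if (M < 1) { ok = false; break; }
      acc += srun[m - 1] * (double)(n - 1) / ((double)M * k * k);
    }
    L[k - 1] = ok ? acc / k : NA_REAL;
  }
}

// [[Rcpp::export(name = ".curve_lengths_cpp")]]
NumericVector curve_lengths_cpp(NumericVector x, int k_max) {
  NumericVector L(k_max);
  curve_lengths_into(&x[0], x.size(), k_max, &L[0]);
  return L;
}

// column-wise variant: returns k_max x ncol matrix of L(k) per column
// [[Rcpp::export(name = ".curve_lengths_mat_cpp")]]
NumericMatrix curve_lengths_mat_cpp(NumericMatrix x, int k_max) {
  const int n = x.nrow(), nc = x.ncol();
  NumericMatrix L(k_max, nc);
  for (int c = 0; c < nc; ++c)
    curve_lengths_into(&x(0, c), n, k_max, &L(0, c));
  return L;
}
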