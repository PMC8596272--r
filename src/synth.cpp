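#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// In-place iterative radix-2 complex FFT (unnormalized; sign = +1 gives the
// e^{+2*pi*i/n} "inverse" convention used for synthesis).  n must be a
// power of two.  No C-level FFT is exported by R's API, and synthesis
// lengths are free to live on a padded power-of-two grid, so the classic
// Cooley-Tukey kernel is all that is needed here.
static void fft_radix2(std::vector<double> &re, std::vector<double> &im,
                       const std::vector<double> &twr,
                       const std::vector<double> &twi) {
  const size_t n = re.size();
  for (size_t i = 1, j = 0; i < n; ++i) {        // bit reversal
    size_t bit = n >> 1;
    for (; j & bit; bit >>= 1) j ^= bit;
    j ^= bit;
    if (i < j) { std::swap(re[i], re[j]); std::swap(im[i], im[j]); }
  }
  for (size_t len = 2; len <= n; len <<= 1) {
    const size_t stride = n / len;
    for (size_t i = 0; i < n; i += len) {
      for (size_t k = 0; k < len / 2; ++k) {
        const size_t a = i + k, b = i + k + len / 2;
        const double cr = twr[k * stride], ci = twi[k * stride];
        const double tr = re[b] * cr - im[b] * ci;
        const double ti = re[b] * ci + im[b] * cr;
        re[b] = re[a] - tr; im[b] = im[a] - ti;
        re[a] += tr;        im[a] += ti;
      }
    }
  }
}

// twiddle table e^{+2*pi*i*k/n}, k = 0..n/2-1 (synthesis direction)
static void fill_twiddles(int n, std::vector<double> &twr,
                          std::vector<double> &twi) {
  twr.resize((size_t)n / 2); twi.resize((size_t)n / 2);
  for (int k = 0; k < n / 2; ++k) {
    const double ang = 2.0 * M_PI * (double)k / (double)n;
    twr[k] = std::cos(ang); twi[k] = std::sin(ang);
  }
}

// Frequency-domain synthesis of band-limited Gaussian signals, written
// directly into a preallocated recording matrix.  For every start row s and
// channel pair (c1, c2), two independent real signals are synthesized from
// their amplitude templates via one complex inverse FFT of length n_fft
// (a power of two >= n; the first n samples of the periodic realization are
// used - a window of a stationary signal is stationary).  Signal 1 rides in
// the real part, signal 2 in the imaginary part, both spectra Hermitian.
// Normal draws come from R's RNG, so the result is a pure function of the
// caller's seed state.
//
// dest:        total_rows x nch matrix (filled in place)
// start_rows0: 0-based start row of each interval
// n:           interval length in samples
// n_fft:       power-of-two synthesis grid length (>= n)
// bins:        1-based DFT bin indices on the n_fft grid (j -> j*fs/n_fft Hz)
// amp:         nb x T matrix of coefficient scales, one column per template
// tpl_of_col0: 0-based template index per channel
// [[Rcpp::export(name = ".synth_fill_cpp")]]
void synth_fill_cpp(NumericMatrix dest, IntegerVector start_rows0, int n,
                    int n_fft, IntegerVector bins, NumericMatrix amp,
                    IntegerVector tpl_of_col0) {
  const int nch = dest.ncol(), nb = bins.size();
  if (tpl_of_col0.size() != nch)
    stop("tpl_of_col must have one entry per channel");
  if (n_fft < n || (n_fft & (n_fft - 1)) != 0)
    stop("n_fft must be a power of two >= n");
  std::vector<double> re((size_t)n_fft), im((size_t)n_fft), twr, twi;
  fill_twiddles(n_fft, twr, twi);

  GetRNGstate();
  for (int s = 0; s < start_rows0.size(); ++s) {
    const int row0 = start_rows0[s];
    for (int c = 0; c < nch; c += 2) {
      std::fill(re.begin(), re.end(), 0.0);
      std::fill(im.begin(), im.end(), 0.0);
      const double *a1 = &amp(0, tpl_of_col0[c]);
      const bool two = (c + 1) < nch;
      const double *a2 = two ? &amp(0, tpl_of_col0[c + 1]) : nullptr;
      for (int j = 0; j < nb; ++j) {
        const int b = bins[j];              // 1-based bin, 0 < b < n_fft/2
        const double x1 = a1[j] * norm_rand(), y1 = a1[j] * norm_rand();
        double re_t = x1, im_t = y1, re_b = x1, im_b = -y1;
        if (two) {
          const double x2 = a2[j] * norm_rand(), y2 = a2[j] * norm_rand();
          // + i * (x2 + i y2) on top, + i * conj on the mirror bin
          re_t -= y2; im_t += x2;
          re_b += y2; im_b += x2;
        }
        re[(size_t)b] += re_t;       im[(size_t)b] += im_t;
        re[(size_t)(n_fft - b)] += re_b; im[(size_t)(n_fft - b)] += im_b;
      }
      fft_radix2(re, im, twr, twi);
      double *col1 = &dest(row0, c);
      for (int t = 0; t < n; ++t) col1[t] = re[(size_t)t];
      if (two) {
        double *col2 = &dest(row0, c + 1);
        for (int t = 0; t < n; ++t) col2[t] = im[(size_t)t];
      }
    }
  }
  PutRNGstate();
}

// Zero-phase (forward-backward) filtering of every column of x with odd
// reflection padding of length `padlen` and steady-state initial conditions
// `zi` (unit-input scaling; rescaled internally by the boundary values).
// [[Rcpp::export(name = ".sosfiltfilt_mat_cpp")]]
NumericMatrix sosfiltfilt_mat_cpp(NumericMatrix x, NumericMatrix sos,
                                  NumericMatrix zi, int padlen) {
  const int n = x.nrow(), nc = x.ncol(), ns = sos.nrow();
  if (padlen >= n) stop("padlen must be smaller than the signal length");
  NumericMatrix out(n, nc);
  const int m = n + 2 * padlen;
  std::vector<double> ext((size_t)m);
  std::vector<double> b0(ns), b1(ns), b2(ns), a1(ns), a2(ns), zi1(ns), zi2(ns),
      w1(ns), w2(ns);
  for (int s = 0; s < ns; ++s) {
    b0[s] = sos(s, 0); b1[s] = sos(s, 1); b2[s] = sos(s, 2);
    a1[s] = sos(s, 4); a2[s] = sos(s, 5);
    zi1[s] = zi(s, 0); zi2[s] = zi(s, 1);
  }

  for (int c = 0; c < nc; ++c) {
    const double *xc = &x(0, c);
    for (int i = 0; i < padlen; ++i) ext[i] = 2.0 * xc[0] - xc[padlen - i];
    for (int i = 0; i < n; ++i) ext[padlen + i] = xc[i];
    for (int i = 0; i < padlen; ++i)
      ext[padlen + n + i] = 2.0 * xc[n - 1] - xc[n - 2 - i];

    for (int pass = 0; pass < 2; ++pass) {
      const double x0 = pass == 0 ? ext[0] : ext[m - 1];
      for (int s = 0; s < ns; ++s) { w1[s] = zi1[s] * x0; w2[s] = zi2[s] * x0; }
      for (int ii = 0; ii < m; ++ii) {
        const int i = pass == 0 ? ii : m - 1 - ii;
        double v = ext[i];
        for (int s = 0; s < ns; ++s) {
          const double yi = b0[s] * v + w1[s];
          w1[s] = b1[s] * v - a1[s] * yi + w2[s];
          w2[s] = b2[s] * v - a2[s] * yi;
          v = yi;
        }
        ext[i] = v;
      }
    }
    for (int i = 0; i < n; ++i) out(i, c) = ext[padlen + i];
  }
  return out;
}
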