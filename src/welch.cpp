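#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Iterative radix-2 Cooley-Tukey FFT on split re/im arrays; n a power of two.
// Twiddles are precomputed; arithmetic is explicit re/im to keep the inner
// loop free of library complex-multiplication calls.
static void fft_radix2(double *re, double *im, int n,
                       const double *twr, const double *twi) {
  for (int i = 1, j = 0; i < n; ++i) {
    int bit = n >> 1;
    for (; j & bit; bit >>= 1) j ^= bit;
    j ^= bit;
    if (i < j) {
      std::swap(re[i], re[j]);
      std::swap(im[i], im[j]);
    }
  }
  for (int len = 2; len <= n; len <<= 1) {
    const int half = len >> 1, step = n / len;
    for (int i = 0; i < n; i += len) {
      for (int k = 0; k < half; ++k) {
        const double wr = twr[k * step], wi = twi[k * step];
        const int a = i + k, b = i + k + half;
        const double vr = re[b] * wr - im[b] * wi;
        const double vi = re[b] * wi + im[b] * wr;
        re[b] = re[a] - vr;
        im[b] = im[a] - vi;
        re[a] += vr;
        im[a] += vi;
      }
    }
  }
}

// Accumulate squared one-sided FFT magnitudes of tapered, zero-padded
// windows for every channel of x (k x n). Two real window-vectors are packed
// into one complex FFT. Returns k x nf matrix of sums of |X|^2 over windows
// (unscaled; nf = nfft/2 + 1).
// [[Rcpp::export]]
NumericMatrix welch_accum_cpp(NumericMatrix x, NumericVector w,
                              IntegerVector starts, int nfft) {
  const int k = x.nrow(), L = w.size(), ns = starts.size();
  if ((nfft & (nfft - 1)) != 0 || nfft < L)
    stop("nfft must be a power of two and >= window length");
  const int nf = nfft / 2 + 1;
  NumericMatrix acc(k, nf);
  double *ap = acc.begin();
  const double *xp = x.begin(), *wp = w.begin();
  std::vector<double> twr(nfft / 2), twi(nfft / 2);
  for (int i = 0; i < nfft / 2; ++i) {
    twr[i] = std::cos(2.0 * M_PI * i / nfft);
    twi[i] = -std::sin(2.0 * M_PI * i / nfft);
  }
  std::vector<double> re(nfft), im(nfft);
  const long njobs = (long)ns * k;
  for (long job = 0; job < njobs; job += 2) {
    const int s1 = (int)(job / k), c1 = (int)(job % k);
    const bool two = job + 1 < njobs;
    const int s2 = two ? (int)((job + 1) / k) : 0;
    const int c2 = two ? (int)((job + 1) % k) : 0;
    const long o1 = (long)(starts[s1] - 1) * 1L;
    const long o2 = two ? (long)(starts[s2] - 1) * 1L : 0;
    for (int t = 0; t < L; ++t) {
      re[t] = xp[c1 + (o1 + t) * (long)k] * wp[t];
      im[t] = two ? xp[c2 + (o2 + t) * (long)k] * wp[t] : 0.0;
    }
    std::fill(re.begin() + L, re.end(), 0.0);
    std::fill(im.begin() + L, im.end(), 0.0);
    fft_radix2(re.data(), im.data(), nfft, twr.data(), twi.data());
    for (int m = 0; m < nf; ++m) {
      const int mc = (nfft - m) & (nfft - 1);
      const double zr = re[m], zi = im[m];
      const double cr = re[mc], ci = -im[mc];
      const double f1r = 0.5 * (zr + cr), f1i = 0.5 * (zi + ci);
      ap[c1 + (long)m * k] += f1r * f1r + f1i * f1i;
      if (two) {
        const double f2r = 0.5 * (zi - ci), f2i = -0.5 * (zr - cr);
        ap[c2 + (long)m * k] += f2r * f2r + f2i * f2i;
      }
    }
  }
  return acc;
}
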