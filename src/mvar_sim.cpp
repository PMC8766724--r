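#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Recursive MVAR simulation with Gaussian innovations drawn inline:
// x_t = sum_r A_r x_{t-r} + e_t, e_t ~ N(0, diag(noise_sd^2)), zero history.
// coeffs: k x k x p array (target, source, lag). Innovations come from a
// Box-Muller transform over R's uniform RNG, so the R seed set before the
// call fully determines the output. Returns the full k x n path; burn-in
// removal happens in R.
// [[Rcpp::export]]
NumericMatrix mvar_sim_cpp(NumericVector coeffs, NumericVector noise_sd,
                           int n) {
  IntegerVector dims = coeffs.attr("dim");
  const int k = dims[0], p = dims[2];
  if (dims[1] != k || noise_sd.size() != k)
    stop("coefficient/noise dimensions disagree");
  NumericMatrix x(k, n);
  double *xp = x.begin();
  const double *A = coeffs.begin();
  const double *sd = noise_sd.begin();
  double spare = 0.0;
  bool have_spare = false;
  for (int t = 0; t < n; ++t) {
    double *xt = xp + (long)t * k;
    for (int i = 0; i < k; ++i) {
      double z;
      if (have_spare) {
        z = spare;
        have_spare = false;
      } else {
        double u1 = unif_rand(), u2 = unif_rand();
        const double r = std::sqrt(-2.0 * std::log(u1));
        const double a = 2.0 * M_PI * u2;
        z = r * std::cos(a);
        spare = r * std::sin(a);
        have_spare = true;
      }
      xt[i] = sd[i] * z;
    }
    const int rmax = t < p ? t : p;
    for (int r = 1; r <= rmax; ++r) {
      const double *Ar = A + (size_t)(r - 1) * k * k;
      const double *xl = xp + (long)(t - r) * k;
      for (int j = 0; j < k; ++j) {
        const double xj = xl[j];
        if (xj != 0.0) {
          const double *col = Ar + (size_t)j * k;
          for (int i = 0; i < k; ++i) xt[i] += col[i] * xj;
        }
      }
    }
  }
  return x;
}
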