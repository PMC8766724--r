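#include <Rcpp.h>
using namespace Rcpp;

// Accumulate the normal equations of the multi-epoch MVAR regression
// directly from the epochs array (k x len x ne), never materializing the
// design matrix. Column order of X: lag r block, channel j within block.
// Returns XtX (kp x kp), XtY (kp x k), YtY (k x k), n_obs.
// [[Rcpp::export]]
List mvar_xtxy_cpp(NumericVector epochs, int p) {
  IntegerVector dims = epochs.attr("dim");
  const int k = dims[0], len = dims[1], ne = dims[2];
  if (len <= p) stop("epochs shorter than the model order");
  const int kp = k * p;
  NumericMatrix XtX(kp, kp), YtX(k, kp), YtY(k, k);
  const double *ep = epochs.begin();
  std::vector<double> row(kp);
  for (int e = 0; e < ne; ++e) {
    const double *base = ep + (size_t)e * k * len;
    for (int t = p; t < len; ++t) {
      // regressor row: lag r -> samples t-r
      for (int r = 1; r <= p; ++r) {
        const double *xl = base + (size_t)(t - r) * k;
        std::copy(xl, xl + k, row.begin() + (r - 1) * k);
      }
      const double *yt = base + (size_t)t * k;
      for (int a = 0; a < kp; ++a) {
        const double ra = row[a];
        if (ra == 0.0) continue;
        double *xc = &XtX(0, a);
        for (int b = 0; b <= a; ++b) xc[b] += row[b] * ra;
        double *yc = &YtX(0, a);
        for (int j = 0; j < k; ++j) yc[j] += ra * yt[j];
      }
      for (int i = 0; i < k; ++i) {
        const double yi = yt[i];
        for (int j = 0; j <= i; ++j) YtY(j, i) += yt[j] * yi;
      }
    }
  }
  // mirror the lower triangles
  for (int a = 0; a < kp; ++a)
    for (int b = 0; b < a; ++b) XtX(a, b) = XtX(b, a);
  for (int i = 0; i < k; ++i)
    for (int j = 0; j < i; ++j) YtY(i, j) = YtY(j, i);
  return List::create(_["XtX"] = XtX, _["YtX"] = YtX, _["YtY"] = YtY,
                      _["n_obs"] = ne * (len - p));
}
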