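#include <Rcpp.h>
using namespace Rcpp;

// Neighborhood max-pooling over a padded neighbor-index matrix.
// idx: n x D, 1-based; column 1 is the vertex itself, further columns its
// bonded neighbors, padded with the vertex's own index.  Returns the pooled
// matrix and, per entry, the source row that supplied the maximum (ties are
// broken toward the vertex itself, then the first listed neighbor), which
// the backward pass uses to route gradients.

// [[Rcpp::export]]
List pool_fwd_cpp(const NumericMatrix& h, const IntegerMatrix& idx) {
  const int n = h.nrow(), f = h.ncol(), D = idx.ncol();
  NumericMatrix p(n, f);
  IntegerMatrix src(n, f);
  for (int r = 0; r < f; ++r) {
    for (int i = 0; i < n; ++i) {
      double best = h(i, r);
      int bi = i;
      for (int d = 1; d < D; ++d) {
        const int j = idx(i, d) - 1;
        if (j == i) continue; // padding
        const double v = h(j, r);
        if (v > best) { best = v; bi = j; }
      }
      p(i, r) = best;
      src(i, r) = bi + 1;
    }
  }
  return List::create(_["p"] = p, _["src"] = src);
}

// Sum of neighbor rows (excluding the vertex itself): the message term of
// the convolution.  Reuses the padded index matrix; padding entries equal
// the row's own index and are skipped.
// [[Rcpp::export]]
NumericMatrix nbr_sum_cpp(const NumericMatrix& x, const IntegerMatrix& idx) {
  const int n = x.nrow(), f = x.ncol(), D = idx.ncol();
  NumericMatrix out(n, f);
  for (int r = 0; r < f; ++r) {
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int d = 1; d < D; ++d) {
        const int j = idx(i, d) - 1;
        if (j == i) continue;
        s += x(j, r);
      }
      out(i, r) = s;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix relu_cpp(const NumericMatrix& z) {
  const int m = z.nrow() * z.ncol();
  NumericMatrix h(z.nrow(), z.ncol());
  const double* zp = z.begin();
  double* hp = h.begin();
  for (int i = 0; i < m; ++i) hp[i] = zp[i] > 0.0 ? zp[i] : 0.0;
  return h;
}

// [[Rcpp::export]]
NumericMatrix relu_grad_cpp(const NumericMatrix& dh, const NumericMatrix& z) {
  const int m = z.nrow() * z.ncol();
  NumericMatrix dz(z.nrow(), z.ncol());
  const double* zp = z.begin();
  const double* dp = dh.begin();
  double* op = dz.begin();
  for (int i = 0; i < m; ++i) op[i] = zp[i] > 0.0 ? dp[i] : 0.0;
  return dz;
}

// [[Rcpp::export]]
NumericMatrix pool_bwd_cpp(const NumericMatrix& dp, const IntegerMatrix& src) {
  const int n = dp.nrow(), f = dp.ncol();
  NumericMatrix dh(n, f);
  for (int r = 0; r < f; ++r)
    for (int i = 0; i < n; ++i)
      dh(src(i, r) - 1, r) += dp(i, r);
  return dh;
}
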