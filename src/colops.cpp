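// Column operations on large genotype matrices, done in place to avoid
// duplicating matrices that can run to hundreds of megabytes.

#include <Rcpp.h>

// Standardize columns of M (population divisor) in place. The caller owns M
// and must pass a freshly allocated matrix. Returns center, scale, excluded.
// [[Rcpp::export(name = ".standardize_cols_inplace")]]
Rcpp::List standardize_cols_inplace(Rcpp::NumericMatrix M) {
  const int n = M.nrow(), m = M.ncol();
  Rcpp::NumericVector center(m), scale(m);
  Rcpp::LogicalVector excluded(m);
  for (int j = 0; j < m; ++j) {
    double s = 0, s2 = 0;
    double* col = &M(0, j);
    for (int i = 0; i < n; ++i) { s += col[i]; s2 += col[i] * col[i]; }
    const double mu = s / n;
    double v = s2 / n - mu * mu;
    if (v < 0) v = 0;
    const bool ex = v < 1e-24;
    const double sd = ex ? 1.0 : std::sqrt(v);
    center[j] = mu; scale[j] = sd; excluded[j] = ex;
    if (ex) {
      for (int i = 0; i < n; ++i) col[i] = 0.0;
    } else {
      const double inv = 1.0 / sd;
      for (int i = 0; i < n; ++i) col[i] = (col[i] - mu) * inv;
    }
  }
  return Rcpp::List::create(Rcpp::Named("center") = center,
                            Rcpp::Named("scale") = scale,
                            Rcpp::Named("excluded") = excluded);
}

// Sum of squares per column without allocating M * M.
// [[Rcpp::export(name = ".colsums_sq")]]
Rcpp::NumericVector colsums_sq(const Rcpp::NumericMatrix& M) {
  const int n = M.nrow(), m = M.ncol();
  Rcpp::NumericVector out(m);
  for (int j = 0; j < m; ++j) {
    double s = 0;
    const double* col = &M(0, j);
    for (int i = 0; i < n; ++i) s += col[i] * col[i];
    out[j] = s;
  }
  return out;
}
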