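#include <Rcpp.h>
using namespace Rcpp;

// Per-edge dot products row_i(A) . row_j(B) for an edge list (1-based),
// without materializing the E x d subsetted matrices.
// [[Rcpp::export(name = ".edge_rowdot_cpp")]]
NumericVector edge_rowdot_cpp(const NumericMatrix& A, const NumericMatrix& B,
                              const IntegerVector& ei, const IntegerVector& ej) {
  const R_xlen_t E = ei.size();
  const int d = A.ncol();
  if (B.ncol() != d) stop("column mismatch in edge_rowdot");
  const int nA = A.nrow(), nB = B.nrow();
  NumericVector out(E);
  const double* a = A.begin();
  const double* b = B.begin();
  for (R_xlen_t e = 0; e < E; ++e) {
    const int i = ei[e] - 1, j = ej[e] - 1;
    double acc = 0.0;
    for (int c = 0; c < d; ++c)
      acc += a[i + (R_xlen_t)c * nA] * b[j + (R_xlen_t)c * nB];
    out[e] = acc;
  }
  return out;
}

// ELU applied elementwise (alpha = 1).
// [[Rcpp::export(name = ".elu_cpp")]]
NumericMatrix elu_cpp(const NumericMatrix& X) {
  NumericMatrix out(X.nrow(), X.ncol());
  const R_xlen_t n = X.size();
  for (R_xlen_t k = 0; k < n; ++k) {
    const double v = X[k];
    out[k] = v > 0 ? v : expm1(v);
  }
  return out;
}

// ELU derivative at the pre-activation: 1 for x > 0, exp(x) otherwise.
// [[Rcpp::export(name = ".elu_grad_cpp")]]
NumericMatrix elu_grad_cpp(const NumericMatrix& X) {
  NumericMatrix out(X.nrow(), X.ncol());
  const R_xlen_t n = X.size();
  for (R_xlen_t k = 0; k < n; ++k) {
    const double v = X[k];
    out[k] = v > 0 ? 1.0 : exp(v);
  }
  return out;
}
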