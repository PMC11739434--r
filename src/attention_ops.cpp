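// Edge-list kernels for the neighbor-attention layers.
//
// Matrices arrive TRANSPOSED (features x cells, column-major), so the
// feature vector of one cell is a contiguous column and every per-edge
// operation is a contiguous dot product or axpy. Edges are directed (self
// loop + both directions of each undirected edge) and sorted by source
// node; `ends` holds the 1-based position of the last edge of each source
// segment. Index vectors are 1-based (straight from R).

#include <Rcpp.h>
using namespace Rcpp;

// x[e] = <At[, ia[e]], Bt[, ib[e]]>
// [[Rcpp::export]]
NumericVector edge_dot(const NumericMatrix& At, const NumericMatrix& Bt,
                       const IntegerVector& ia, const IntegerVector& ib) {
  const int m = ia.size(), d = At.nrow();
  const double* a = At.begin();
  const double* b = Bt.begin();
  const int* pia = ia.begin();
  const int* pib = ib.begin();
  NumericVector out(m);
  double* o = out.begin();
  for (int e = 0; e < m; ++e) {
    const double* ac = a + (R_xlen_t)(pia[e] - 1) * d;
    const double* bc = b + (R_xlen_t)(pib[e] - 1) * d;
    double s = 0.0;
    for (int k = 0; k < d; ++k) s += ac[k] * bc[k];
    o[e] = s;
  }
  return out;
}

// max-shifted softmax within contiguous segments ending at `ends`
// [[Rcpp::export]]
NumericVector edge_softmax(const NumericVector& e,
                           const IntegerVector& ends) {
  const int n = ends.size();
  NumericVector a(e.size());
  int lo = 0;
  for (int g = 0; g < n; ++g) {
    const int hi = ends[g];            // 1-based end -> exclusive bound
    double mx = R_NegInf;
    for (int j = lo; j < hi; ++j) mx = std::max(mx, e[j]);
    double z = 0.0;
    for (int j = lo; j < hi; ++j) {
      a[j] = std::exp(e[j] - mx);
      z += a[j];
    }
    for (int j = lo; j < hi; ++j) a[j] /= z;
    lo = hi;
  }
  return a;
}

// out[, iw[e]] += w[e] * At[, ia[e]]   (out is d x n)
// [[Rcpp::export]]
NumericMatrix edge_scatter(const NumericMatrix& At, const IntegerVector& ia,
                           const NumericVector& w, const IntegerVector& iw,
                           const int n) {
  const int m = ia.size(), d = At.nrow();
  NumericMatrix out(d, n);
  const double* a = At.begin();
  const int* pia = ia.begin();
  const int* piw = iw.begin();
  const double* pw = w.begin();
  double* o = out.begin();
  for (int e = 0; e < m; ++e) {
    const double* ac = a + (R_xlen_t)(pia[e] - 1) * d;
    double* oc = o + (R_xlen_t)(piw[e] - 1) * d;
    const double we = pw[e];
    for (int k = 0; k < d; ++k) oc[k] += we * ac[k];
  }
  return out;
}

// segment sums of a vector over contiguous segments ending at `ends`
// [[Rcpp::export]]
NumericVector vec_segment_sum(const NumericVector& x,
                              const IntegerVector& ends) {
  const int n = ends.size();
  NumericVector out(n);
  int lo = 0;
  for (int g = 0; g < n; ++g) {
    const int hi = ends[g];
    double s = 0.0;
    for (int j = lo; j < hi; ++j) s += x[j];
    out[g] = s;
    lo = hi;
  }
  return out;
}
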