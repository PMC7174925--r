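#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// Mean hierarchical-softmax log-probability over directed training pairs.
// emb, nodes: dim x n_tokens / dim x n_internal (column = one vector).
// pin/ptg: 0-based input/target token indices. path_flat/code_flat hold the
// root-first internal-node indices (0-based) and bits of every token's
// Huffman path; offset[v]..offset[v+1]-1 delimits token v's slice.
// [[Rcpp::export]]
double hs_mean_loglik_cpp(const NumericMatrix& emb, const NumericMatrix& nodes,
                          const IntegerVector& pin, const IntegerVector& ptg,
                          const IntegerVector& path_flat,
                          const IntegerVector& code_flat,
                          const IntegerVector& offset) {
  const int dim = emb.nrow();
  const R_xlen_t n_pairs = pin.size();
  if (n_pairs == 0) return NA_REAL;
  double total = 0.0;
  for (R_xlen_t p = 0; p < n_pairs; ++p) {
    const double* ej = &emb(0, pin[p]);
    const int w = ptg[p];
    double lp = 0.0;
    for (int l = offset[w]; l < offset[w + 1]; ++l) {
      const double* vn = &nodes(0, path_flat[l]);
      double x = 0.0;
      for (int d = 0; d < dim; ++d) x += vn[d] * ej[d];
      const double s = code_flat[l] == 0 ? x : -x;
      // log(sigmoid(s)), numerically stable
      lp += s < 0 ? s - std::log1p(std::exp(s)) : -std::log1p(std::exp(-s));
    }
    total += lp;
  }
  return total / static_cast<double>(n_pairs);
}

// Sequential SGD on the hierarchical-softmax objective. Pairs are visited
// in the given order each epoch; the learning rate decays linearly from
// alpha0 to min_alpha over all epochs * n_pairs updates. emb and nodes are
// updated in place. Returns the mean log-likelihood after each epoch.
// [[Rcpp::export]]
NumericVector msg_sgd_cpp(NumericMatrix emb, NumericMatrix nodes,
                          const IntegerVector& pin, const IntegerVector& ptg,
                          const IntegerVector& path_flat,
                          const IntegerVector& code_flat,
                          const IntegerVector& offset,
                          int epochs, double alpha0, double min_alpha) {
  const int dim = emb.nrow();
  const R_xlen_t n_pairs = pin.size();
  const double total_updates = static_cast<double>(n_pairs) * epochs;
  std::vector<double> neu1e(dim);
  NumericVector objective(epochs);
  R_xlen_t t = 0;
  for (int e = 0; e < epochs; ++e) {
    for (R_xlen_t p = 0; p < n_pairs; ++p, ++t) {
      double alpha = alpha0 * (1.0 - static_cast<double>(t) / total_updates);
      if (alpha < min_alpha) alpha = min_alpha;
      double* ej = &emb(0, pin[p]);
      const int w = ptg[p];
      std::fill(neu1e.begin(), neu1e.end(), 0.0);
      for (int l = offset[w]; l < offset[w + 1]; ++l) {
        double* vn = &nodes(0, path_flat[l]);
        double x = 0.0;
        for (int d = 0; d < dim; ++d) x += vn[d] * ej[d];
        const double g = (1.0 - code_flat[l] - sigmoid(x)) * alpha;
        for (int d = 0; d < dim; ++d) neu1e[d] += g * vn[d];
        for (int d = 0; d < dim; ++d) vn[d] += g * ej[d];
      }
      for (int d = 0; d < dim; ++d) ej[d] += neu1e[d];
    }
    objective[e] = hs_mean_loglik_cpp(emb, nodes, pin, ptg,
                                      path_flat, code_flat, offset);
  }
  return objective;
}
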