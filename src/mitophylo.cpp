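#include <Rcpp.h>
using namespace Rcpp;

// Node numbering convention shared with R/itree.R:
//   leaves 1..n, internal nodes n+1..m (m = 2n-1 for a rooted binary tree),
//   `kids` is an m x 2 integer matrix (0 for leaves), `post` lists internal
//   nodes in postorder (children before parents), ending at the root.

// Weighted Fitch length over site patterns.
// `states`: npat x n integer matrix of 4-bit sets (A=1, C=2, G=4, T=8;
// gap/unknown = 15). Returns sum over patterns of weight * changes.
// [[Rcpp::export]]
double fitch_count(const IntegerMatrix& states, const NumericVector& weights,
                   const IntegerVector& post, const IntegerMatrix& kids) {
  const int npat = states.nrow();
  const int n = states.ncol();
  const int m = kids.nrow();
  std::vector<int> set(static_cast<size_t>(npat) * m);
  for (int v = 0; v < n; ++v)
    for (int p = 0; p < npat; ++p) set[static_cast<size_t>(v) * npat + p] = states(p, v);
  std::vector<double> changes(npat, 0.0);
  for (int k = 0; k < post.size(); ++k) {
    const int v = post[k] - 1;
    const int l = kids(v, 0) - 1, r = kids(v, 1) - 1;
    const int* sl = &set[static_cast<size_t>(l) * npat];
    const int* sr = &set[static_cast<size_t>(r) * npat];
    int* sv = &set[static_cast<size_t>(v) * npat];
    for (int p = 0; p < npat; ++p) {
      const int inter = sl[p] & sr[p];
      if (inter) sv[p] = inter;
      else { sv[p] = sl[p] | sr[p]; changes[p] += 1.0; }
    }
  }
  double total = 0.0;
  for (int p = 0; p < npat; ++p) total += weights[p] * changes[p];
  return total;
}

// Felsenstein pruning for the variable-rate class of GTR(+I).
// `leafbits`: npat x n bitmask matrix as above; a leaf's conditional
// likelihood is the 0/1 indicator of its ambiguity set.
// `P`: 16*m vector; entries 16*v .. 16*v+15 hold the 4x4 transition matrix
// (column-major, P[from,to]) for the edge above node v+1 (root slot unused).
// Returns per-pattern log-likelihoods (log scaled to avoid underflow).
// [[Rcpp::export]]
NumericVector pruning_loglik_patterns(const IntegerMatrix& leafbits,
                                      const IntegerVector& post,
                                      const IntegerMatrix& kids,
                                      const NumericVector& P,
                                      const NumericVector& pi) {
  const int npat = leafbits.nrow();
  const int n = leafbits.ncol();
  const int m = kids.nrow();
  std::vector<double> part(static_cast<size_t>(npat) * m * 4);
  for (int v = 0; v < n; ++v) {
    double* pv = &part[static_cast<size_t>(v) * npat * 4];
    for (int p = 0; p < npat; ++p) {
      const int b = leafbits(p, v);
      for (int s = 0; s < 4; ++s) pv[p * 4 + s] = (b >> s) & 1 ? 1.0 : 0.0;
    }
  }
  NumericVector logscale(npat);
  const int root = post[post.size() - 1] - 1;
  for (int k = 0; k < post.size(); ++k) {
    const int v = post[k] - 1;
    double* pv = &part[static_cast<size_t>(v) * npat * 4];
    for (int p = 0; p < npat; ++p)
      pv[p * 4] = pv[p * 4 + 1] = pv[p * 4 + 2] = pv[p * 4 + 3] = 1.0;
    for (int ci = 0; ci < 2; ++ci) {
      const int c = kids(v, ci) - 1;
      const double* Pc = &P[16 * c];
      const double* pc = &part[static_cast<size_t>(c) * npat * 4];
      for (int p = 0; p < npat; ++p) {
        for (int s = 0; s < 4; ++s) {
          double acc = 0.0;
          for (int t = 0; t < 4; ++t) acc += Pc[s + 4 * t] * pc[p * 4 + t];
          pv[p * 4 + s] *= acc;
        }
      }
    }
    if (v != root) {
      for (int p = 0; p < npat; ++p) {
        double mx = pv[p * 4];
        for (int s = 1; s < 4; ++s) if (pv[p * 4 + s] > mx) mx = pv[p * 4 + s];
        if (mx > 0 && mx < 1e-200) {
          for (int s = 0; s < 4; ++s) pv[p * 4 + s] /= mx;
          logscale[p] += std::log(mx);
        }
      }
    }
  }
  NumericVector out(npat);
  const double* pr = &part[static_cast<size_t>(root) * npat * 4];
  for (int p = 0; p < npat; ++p) {
    double L = 0.0;
    for (int s = 0; s < 4; ++s) L += pi[s] * pr[p * 4 + s];
    out[p] = (L > 0 ? std::log(L) : R_NegInf) + logscale[p];
  }
  return out;
}
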