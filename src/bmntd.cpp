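#include <Rcpp.h>
using namespace Rcpp;

// Between-community mean nearest-taxon distance for one pair.
// ix, iy: 0-based row/column indices of the taxa present in each community;
// wx, wy: matching weights, each summing to 1 (uniform for presence-based).
// [[Rcpp::export]]
double cpp_bmntd_pair(const NumericMatrix& d,
                      const IntegerVector& ix, const IntegerVector& iy,
                      const NumericVector& wx, const NumericVector& wy) {
  const int nx = ix.size(), ny = iy.size();
  double sx = 0.0, sy = 0.0;
  for (int a = 0; a < nx; ++a) {
    double m = R_PosInf;
    for (int b = 0; b < ny; ++b) {
      const double v = d(ix[a], iy[b]);
      if (v < m) m = v;
    }
    sx += wx[a] * m;
  }
  for (int b = 0; b < ny; ++b) {
    double m = R_PosInf;
    for (int a = 0; a < nx; ++a) {
      const double v = d(iy[b], ix[a]);
      if (v < m) m = v;
    }
    sy += wy[b] * m;
  }
  return 0.5 * (sx + sy);
}

// All-pairs betaMNTD under a set of tip permutations.
// d: G x G patristic matrix over the regional taxa;
// supports: per-sample 0-based indices of present taxa;
// weights: per-sample weights summing to 1;
// perms: G x R matrix, each column a 0-based permutation of 0..G-1 giving the
//        shuffled tip assignment (identity column = observed values).
// Returns an R x npairs matrix, pairs ordered (0,1),(0,2),...,(S-2,S-1).
// For each permutation and sample j we precompute, for every regional taxon t,
// the minimum distance from tip perm[t] to sample j's (permuted) tip set, so
// each pair costs O(n_i + n_j) after an O(G * n_j) sweep per sample.
// [[Rcpp::export]]
NumericMatrix cpp_bmntd_null(const NumericMatrix& d,
                             const List& supports, const List& weights,
                             const IntegerMatrix& perms) {
  const int G = d.nrow(), S = supports.size(), R = perms.ncol();
  const int npairs = S * (S - 1) / 2;
  NumericMatrix out(R, npairs);
  std::vector<std::vector<double> > minv(S, std::vector<double>(G));

  for (int r = 0; r < R; ++r) {
    const IntegerMatrix::ConstColumn p = perms(_, r);
    for (int s = 0; s < S; ++s) {
      const IntegerVector supp = supports[s];
      const int ns = supp.size();
      for (int t = 0; t < G; ++t) {
        const int pt = p[t];
        double m = R_PosInf;
        for (int b = 0; b < ns; ++b) {
          const double v = d(pt, p[supp[b]]);
          if (v < m) m = v;
        }
        minv[s][t] = m;
      }
    }
    int k = 0;
    for (int i = 0; i < S; ++i) {
      const IntegerVector si = supports[i];
      const NumericVector wi = weights[i];
      for (int j = i + 1; j < S; ++j, ++k) {
        const IntegerVector sj = supports[j];
        const NumericVector wj = weights[j];
        double sx = 0.0, sy = 0.0;
        for (int a = 0; a < si.size(); ++a) sx += wi[a] * minv[j][si[a]];
        for (int b = 0; b < sj.size(); ++b) sy += wj[b] * minv[i][sj[b]];
        out(r, k) = 0.5 * (sx + sy);
      }
    }
    if ((r & 31) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
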