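// PC-stable skeleton search with Fisher-z partial-correlation tests.
// Mirrors the pure-R reference engine exactly (same edge order, same side
// order, same lexicographic subset enumeration) so the two can be compared
// bit-for-bit in tests.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// recursive closed-form partial correlation for small conditioning sets:
// rho(x, y | S) = (rho(x,y|S') - rho(x,z|S') rho(y,z|S')) /
//                 sqrt((1 - rho(x,z|S')^2)(1 - rho(y,z|S')^2)), z in S.
static double parcor_rec(const arma::mat& C, int x, int y,
                         const int* S, int l) {
  if (l == 0) return C(x, y);
  const int z = S[l - 1];
  const double rxy = parcor_rec(C, x, y, S, l - 1);
  const double rxz = parcor_rec(C, x, z, S, l - 1);
  const double ryz = parcor_rec(C, y, z, S, l - 1);
  const double den = (1.0 - rxz * rxz) * (1.0 - ryz * ryz);
  if (den <= 1e-20) return 1.0;  // degenerate conditioning
  return (rxy - rxz * ryz) / std::sqrt(den);
}

// partial correlation of nodes 0 and 1 of the submatrix on idx; closed-form
// recursion for small sets, precision-matrix inversion beyond
static double parcor(const arma::mat& C, const arma::uvec& idx, double tol) {
  const int l = (int)idx.n_elem - 2;
  double r;
  if (l <= 3) {
    std::vector<int> S(l);
    for (int k = 0; k < l; ++k) S[k] = (int)idx(2 + k);
    r = parcor_rec(C, (int)idx(0), (int)idx(1), S.data(), l);
  } else {
    arma::mat sub = C.submat(idx, idx);
    arma::mat P;
    bool ok = arma::inv_sympd(P, sub);
    if (!ok) ok = arma::inv(P, sub);
    if (!ok) P = arma::pinv(sub, tol);
    double den = P(0, 0) * P(1, 1);
    if (den <= 0.0) return 1.0;  // degenerate: treat as maximally dependent
    r = -P(0, 1) / std::sqrt(den);
  }
  if (r > 1.0) r = 1.0;
  if (r < -1.0) r = -1.0;
  return r;
}

// [[Rcpp::export]]
List pc_skeleton_cpp(const arma::mat& corr, const int n, const double alpha,
                     const int max_cond) {
  const int p = corr.n_rows;
  const double crit = R::qnorm(1.0 - alpha / 2.0, 0.0, 1.0, 1, 0);
  LogicalMatrix adj(p, p);
  for (int i = 0; i < p; ++i)
    for (int j = 0; j < p; ++j) adj(i, j) = (i != j);

  std::vector<int> sep_i, sep_j;
  std::vector<std::vector<int>> sep_sets;

  int l = 0;
  for (;;) {
    if (n - l - 3 <= 0) break;          // Fisher-z undefined at this level
    // level-start snapshot of neighborhoods (PC-stable)
    std::vector<std::vector<int>> nbrs(p);
    for (int i = 0; i < p; ++i)
      for (int j = 0; j < p; ++j)
        if (adj(i, j)) nbrs[i].push_back(j);

    const double sq = std::sqrt((double)(n - l - 3));
    for (int i = 0; i < p - 1; ++i) {
      for (int j = i + 1; j < p; ++j) {
        if (!adj(i, j)) continue;
        bool removed = false;
        for (int side = 0; side < 2 && !removed; ++side) {
          const int a = side == 0 ? i : j;
          const int b = side == 0 ? j : i;
          std::vector<int> nb;
          nb.reserve(nbrs[a].size());
          for (int v : nbrs[a]) if (v != b) nb.push_back(v);
          const int m = (int)nb.size();
          if (m < l) continue;
          // lexicographic combinations of size l from nb
          std::vector<int> comb(l);
          for (int k = 0; k < l; ++k) comb[k] = k;
          for (;;) {
            arma::uvec idx(2 + l);
            idx(0) = a; idx(1) = b;
            for (int k = 0; k < l; ++k) idx(2 + k) = nb[comb[k]];
            double r = parcor(corr, idx, 1e-10);
            double z = (std::abs(r) >= 1.0) ? R_PosInf
              : 0.5 * std::log((1.0 + r) / (1.0 - r));
            if (sq * std::abs(z) <= crit) {   // independent: remove edge
              adj(i, j) = adj(j, i) = false;
              sep_i.push_back(i + 1);
              sep_j.push_back(j + 1);
              std::vector<int> S(l);
              for (int k = 0; k < l; ++k) S[k] = nb[comb[k]] + 1;
              sep_sets.push_back(S);
              removed = true;
              break;
            }
            if (l == 0) break;
            // next combination
            int k = l - 1;
            while (k >= 0 && comb[k] == m - l + k) --k;
            if (k < 0) break;
            ++comb[k];
            for (int t = k + 1; t < l; ++t) comb[t] = comb[t - 1] + 1;
          }
        }
      }
    }
    ++l;
    if (l > max_cond) break;
    bool more = false;
    for (int i = 0; i < p && !more; ++i) {
      int deg = 0;
      for (int j = 0; j < p; ++j) if (adj(i, j)) ++deg;
      if (deg >= l + 1) more = true;   // some edge has |adj(a)\{b}| >= l
    }
    if (!more) break;
  }

  List sets(sep_sets.size());
  for (size_t k = 0; k < sep_sets.size(); ++k)
    sets[k] = IntegerVector(sep_sets[k].begin(), sep_sets[k].end());
  return List::create(_["adj"] = adj,
                      _["sep_i"] = IntegerVector(sep_i.begin(), sep_i.end()),
                      _["sep_j"] = IntegerVector(sep_j.begin(), sep_j.end()),
                      _["sep_sets"] = sets);
}
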