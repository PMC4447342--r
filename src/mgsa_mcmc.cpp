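// Metropolis-Gibbs sampler for the Bayesian set-activation (MGSA-style)
// model: hidden item state h_i = 1 iff item i belongs to >= 1 active set;
// observation flips with false-positive rate alpha (P(on | h = 0)) and
// false-negative rate beta (P(off | h = 1)); activation prior Bernoulli(p).
// alpha, beta and p move over discrete grids with uniform priors.
// Uses R's RNG so set.seed() in R controls the chain.
#include <Rcpp.h>
#include <numeric>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List mgsa_mcmc_cpp(const List sets, const int n_universe,
                   const LogicalVector observed,
                   const NumericVector alpha_grid,
                   const NumericVector beta_grid,
                   const NumericVector p_grid,
                   const int n_iter, const int burnin) {
  const int m = sets.size();
  std::vector<std::vector<int>> mem(m);   // 0-based item indices per set
  for (int j = 0; j < m; ++j) {
    IntegerVector s = sets[j];
    mem[j].assign(s.begin(), s.end());
  }
  const int n_on_total = std::accumulate(observed.begin(), observed.end(), 0);
  const int n_off_total = n_universe - n_on_total;

  std::vector<int> cover(n_universe, 0);
  std::vector<char> active(m, 0);
  int k_active = 0;
  int h1_on = 0, h1_off = 0;              // covered items, by observation

  auto loglik = [&](double a, double b) {
    const int h0_on = n_on_total - h1_on;
    const int h0_off = n_off_total - h1_off;
    return h0_on * std::log(a) + h0_off * std::log1p(-a) +
           h1_off * std::log(b) + h1_on * std::log1p(-b);
  };
  auto logprior = [&](double p) {
    return k_active * std::log(p) + (m - k_active) * std::log1p(-p);
  };
  // toggle set j, updating cover counts and h1 tallies
  auto toggle = [&](int j) {
    const int d = active[j] ? -1 : 1;
    for (int it : mem[j]) {
      const int before = cover[it];
      cover[it] += d;
      const bool was = before > 0, is = cover[it] > 0;
      if (was != is) {
        const int dd = is ? 1 : -1;
        if (observed[it]) h1_on += dd; else h1_off += dd;
      }
    }
    active[j] = !active[j];
    k_active += d;
  };

  int ia = 0, ib = 0, ip = 0;             // current grid indices
  const int na = alpha_grid.size(), nb = beta_grid.size(),
            np = p_grid.size();
  double cur_ll = loglik(alpha_grid[ia], beta_grid[ib]);
  double cur_lp = logprior(p_grid[ip]);

  NumericVector post(m);
  NumericVector par_post(3);              // posterior means of alpha, beta, p
  long kept = 0;
  long accepted = 0;

  // Move-type probabilities are state-independent (required for detailed
  // balance): moves that are impossible in the current state are no-ops.
  for (int iter = 0; iter < n_iter; ++iter) {
    const double u = unif_rand();
    if (u < 0.45) {                       // single-bit toggle
      int j1 = (int)(unif_rand() * m); if (j1 >= m) j1 = m - 1;
      toggle(j1);
      const double new_ll = loglik(alpha_grid[ia], beta_grid[ib]);
      const double new_lp = logprior(p_grid[ip]);
      const double lr = (new_ll + new_lp) - (cur_ll + cur_lp);
      if (lr >= 0 || unif_rand() < std::exp(lr)) {
        cur_ll = new_ll; cur_lp = new_lp; ++accepted;
      } else {
        toggle(j1);
      }
    } else if (u < 0.75) {                // active/inactive swap
      if (k_active > 0 && k_active < m) {
        int ka = (int)(unif_rand() * k_active);
        if (ka >= k_active) ka = k_active - 1;
        int ki = (int)(unif_rand() * (m - k_active));
        if (ki >= m - k_active) ki = m - k_active - 1;
        int j1 = -1, j2 = -1, ca = -1, ci = -1;
        for (int j = 0; j < m; ++j) {
          if (active[j]) { if (++ca == ka) j1 = j; }
          else { if (++ci == ki) j2 = j; }
        }
        toggle(j1);
        toggle(j2);
        const double new_ll = loglik(alpha_grid[ia], beta_grid[ib]);
        const double lr = new_ll - cur_ll;   // prior unchanged (same k)
        if (lr >= 0 || unif_rand() < std::exp(lr)) {
          cur_ll = new_ll; ++accepted;
        } else {
          toggle(j2);
          toggle(j1);
        }
      }
    } else {                              // parameter move on one grid
      int which = (int)(unif_rand() * 3); if (which > 2) which = 2;
      const int len = which == 0 ? na : (which == 1 ? nb : np);
      if (len > 1) {
        int prop = (int)(unif_rand() * len); if (prop >= len) prop = len - 1;
        const int old = which == 0 ? ia : (which == 1 ? ib : ip);
        if (which == 0) ia = prop; else if (which == 1) ib = prop;
        else ip = prop;
        const double new_ll = loglik(alpha_grid[ia], beta_grid[ib]);
        const double new_lp = logprior(p_grid[ip]);
        const double lr = (new_ll + new_lp) - (cur_ll + cur_lp);
        if (lr >= 0 || unif_rand() < std::exp(lr)) {
          cur_ll = new_ll; cur_lp = new_lp; ++accepted;
        } else {
          if (which == 0) ia = old; else if (which == 1) ib = old;
          else ip = old;
        }
      }
    }
    if (iter >= burnin) {
      for (int j = 0; j < m; ++j) post[j] += active[j];
      par_post[0] += alpha_grid[ia];
      par_post[1] += beta_grid[ib];
      par_post[2] += p_grid[ip];
      ++kept;
    }
  }
  for (int j = 0; j < m; ++j) post[j] /= (double)kept;
  for (int t = 0; t < 3; ++t) par_post[t] /= (double)kept;
  return List::create(_["posterior"] = post,
                      _["param_means"] = par_post,
                      _["acceptance_rate"] = (double)accepted / n_iter);
}
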