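// Systematic-scan Gibbs sampler over binary single-cell contact states.
// Likelihood: per-contact active counts k_j ~ Binomial(n_cells, f_j).
// Prior per cell: active contact j contributes logit(f_j) (base odds) plus
// log_boost when at least one DAG parent is active, minus a sparsity penalty;
// states activating a forbidden subset have prior mass zero.
#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {
inline bool parent_active(const std::vector<int> &st, int n_cells, int cell,
                          const std::vector<int> &par, int skip) {
  for (int p : par)
    if (p != skip && st[(size_t)p * n_cells + cell]) return true;
  return false;
}
} // namespace

// [[Rcpp::export]]
List gibbs_cpp(IntegerMatrix init, NumericVector logit_f, NumericMatrix lbinom,
               List parents, List forbidden, double log_boost, double sparsity,
               int n_sweeps, int burn_in, int record_every, double seed) {
  const int n_cells = init.nrow(), M = init.ncol();
  std::mt19937_64 eng((unsigned long)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  // column-major flat state: st[j * n_cells + c]
  std::vector<int> st((size_t)n_cells * M);
  std::vector<int> k(M, 0);
  for (int j = 0; j < M; ++j)
    for (int c = 0; c < n_cells; ++c) {
      st[(size_t)j * n_cells + c] = init(c, j);
      k[j] += init(c, j);
    }

  std::vector<std::vector<int>> par(M), chd(M);
  for (int j = 0; j < M; ++j) {
    IntegerVector pv = parents[j];
    for (int x : pv) par[j].push_back(x - 1);
  }
  for (int j = 0; j < M; ++j)
    for (int p : par[j]) chd[p].push_back(j);

  std::vector<std::vector<int>> forb;
  std::vector<std::vector<int>> forb_of(M); // forbidden set ids touching j
  for (int q = 0; q < forbidden.size(); ++q) {
    IntegerVector fv = forbidden[q];
    std::vector<int> s;
    for (int x : fv) s.push_back(x - 1);
    forb.push_back(s);
    for (int x : s) forb_of[x].push_back(q);
  }

  auto prior_cell_term = [&](int cell, int j) {
    double v = logit_f[j] - sparsity;
    if (parent_active(st, n_cells, cell, par[j], -1)) v += log_boost;
    return v;
  };

  auto total_log_post = [&]() {
    double lp = 0.0;
    for (int j = 0; j < M; ++j) lp += lbinom(k[j], j);
    for (int c = 0; c < n_cells; ++c)
      for (int j = 0; j < M; ++j)
        if (st[(size_t)j * n_cells + c]) lp += prior_cell_term(c, j);
    return lp;
  };

  NumericVector trace(n_sweeps);
  std::vector<int> samples;
  int n_samples = 0;

  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    for (int c = 0; c < n_cells; ++c) {
      for (int j = 0; j < M; ++j) {
        int cur = st[(size_t)j * n_cells + c];
        // can contact j be ON in cell c without completing a forbidden set?
        bool on_allowed = true;
        for (int q : forb_of[j]) {
          bool others = true;
          for (int x : forb[q])
            if (x != j && !st[(size_t)x * n_cells + c]) {
              others = false;
              break;
            }
          if (others) {
            on_allowed = false;
            break;
          }
        }
        double p_on;
        if (!on_allowed) {
          p_on = 0.0;
        } else {
          int k_off = k[j] - cur; // count with s_cj = 0
          double d = prior_cell_term(c, j) +
                     lbinom(k_off + 1, j) - lbinom(k_off, j);
          // children of j whose boost indicator flips with s_cj
          st[(size_t)j * n_cells + c] = 1;
          for (int m : chd[j]) {
            if (!st[(size_t)m * n_cells + c]) continue;
            if (!parent_active(st, n_cells, c, par[m], j)) d += log_boost;
          }
          st[(size_t)j * n_cells + c] = cur;
          p_on = 1.0 / (1.0 + std::exp(-d));
        }
        int nv = (unif(eng) < p_on) ? 1 : 0;
        if (nv != cur) {
          st[(size_t)j * n_cells + c] = nv;
          k[j] += nv - cur;
        }
      }
    }
    trace[sweep] = total_log_post();
    if (record_every > 0 && sweep >= burn_in &&
        (sweep - burn_in) % record_every == 0) {
      samples.insert(samples.end(), st.begin(), st.end());
      ++n_samples;
    }
  }

  IntegerMatrix out(n_cells, M);
  for (int j = 0; j < M; ++j)
    for (int c = 0; c < n_cells; ++c) out(c, j) = st[(size_t)j * n_cells + c];

  IntegerMatrix smp(n_samples, n_cells * M);
  for (int r = 0; r < n_samples; ++r)
    for (int j = 0; j < M; ++j)
      for (int c = 0; c < n_cells; ++c)
        smp(r, (size_t)j * n_cells + c) =
            samples[(size_t)r * n_cells * M + (size_t)j * n_cells + c];

  return List::create(_["states"] = out, _["trace"] = trace,
                      _["samples"] = smp);
}
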