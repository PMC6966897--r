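// Sequential Monte Carlo growth of confined self-avoiding bead chains, plus
// weighted contact/distance tallies used throughout the package.
#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Rng {
  std::mt19937_64 eng;
  std::uniform_real_distribution<double> unif{0.0, 1.0};
  explicit Rng(unsigned long seed) : eng(seed) {}
  double runif() { return unif(eng); }
  // uniform direction on the unit sphere (Marsaglia)
  void dir(double *d) {
    double x1, x2, s;
    do {
      x1 = 2.0 * runif() - 1.0;
      x2 = 2.0 * runif() - 1.0;
      s = x1 * x1 + x2 * x2;
    } while (s >= 1.0);
    double r = 2.0 * std::sqrt(1.0 - s);
    d[0] = x1 * r;
    d[1] = x2 * r;
    d[2] = 1.0 - 2.0 * s;
  }
  // uniform point in a sphere of given radius
  void in_sphere(double radius, double *p) {
    double d[3];
    dir(d);
    double u = std::cbrt(runif());
    for (int k = 0; k < 3; ++k) p[k] = radius * u * d[k];
  }
};

inline double sqdist(const double *a, const double *b) {
  double dx = a[0] - b[0], dy = a[1] - b[1], dz = a[2] - b[2];
  return dx * dx + dy * dy + dz * dz;
}

// systematic resampling of n indices proportional to w (w >= 0, sum > 0)
void systematic_resample(const std::vector<double> &w, int n, Rng &rng,
                         std::vector<int> &out) {
  double tot = 0.0;
  for (double x : w) tot += x;
  double u = rng.runif() * tot / n;
  double cum = 0.0;
  int j = 0;
  out.resize(n);
  for (int i = 0; i < n; ++i) {
    double target = u + i * (tot / (double)n);
    while (cum + w[j] < target && j + 1 < (int)w.size()) {
      cum += w[j];
      ++j;
    }
    out[i] = j;
  }
}

} // namespace

// Grow a population of self-avoiding chains inside a confining sphere.
// Constraints are 0-based bin pairs (i < j) that must end <= threshold apart.
// Returns coords (n_bins x 3 x n_chains), per-chain log importance weights,
// and growth diagnostics. success == false flags persistent dead-ends.
// [[Rcpp::export]]
List smc_sample_cpp(int n_bins, int n_chains, double bond, double fiber,
                    double threshold, double radius,
                    IntegerMatrix constraints, int n_cand,
                    int checkpoint_every, int max_restarts, double seed,
                    bool resample) {
  Rng rng((unsigned long)seed);
  const int nc = constraints.nrow();
  const double fiber2 = fiber * fiber, thr2 = threshold * threshold;

  std::vector<double> coords((size_t)n_chains * n_bins * 3, 0.0);
  std::vector<double> lw(n_chains, 0.0);
  std::vector<bool> dead(n_chains, false);
  std::vector<double> cand((size_t)n_cand * 3);

  long dead_ends = 0, starts = 0;
  int restarts = 0;
  int longest_partial = 0;
  bool success = true;

  auto chain_ptr = [&](int c) { return &coords[(size_t)c * n_bins * 3]; };

  for (;;) { // population (re)starts
    starts += n_chains;
    std::fill(lw.begin(), lw.end(), 0.0);
    std::fill(dead.begin(), dead.end(), false);
    bool collapsed = false;

    for (int c = 0; c < n_chains; ++c) rng.in_sphere(radius, chain_ptr(c));

    for (int t = 1; t < n_bins && !collapsed; ++t) {
      for (int c = 0; c < n_chains; ++c) {
        if (dead[c]) continue;
        double *ch = chain_ptr(c);
        const double *prev = ch + (size_t)(t - 1) * 3;
        int n_valid = 0;
        for (int k = 0; k < n_cand; ++k) {
          double d[3];
          rng.dir(d);
          double x[3] = {prev[0] + bond * d[0], prev[1] + bond * d[1],
                         prev[2] + bond * d[2]};
          if (x[0] * x[0] + x[1] * x[1] + x[2] * x[2] > radius * radius)
            continue;
          bool ok = true;
          for (int b = 0; b < t - 1 && ok; ++b)
            if (sqdist(x, ch + (size_t)b * 3) < fiber2) ok = false;
          // constraint satisfaction / look-ahead pruning
          for (int q = 0; q < nc && ok; ++q) {
            int a = constraints(q, 0), b = constraints(q, 1);
            if (b == t) {
              if (sqdist(x, ch + (size_t)a * 3) > thr2) ok = false;
            } else if (a < t && b > t) {
              double reach = threshold + bond * (double)(b - t);
              if (sqdist(x, ch + (size_t)a * 3) > reach * reach) ok = false;
            }
          }
          if (!ok) continue;
          cand[(size_t)n_valid * 3] = x[0];
          cand[(size_t)n_valid * 3 + 1] = x[1];
          cand[(size_t)n_valid * 3 + 2] = x[2];
          ++n_valid;
        }
        if (n_valid == 0) {
          dead[c] = true;
          ++dead_ends;
          if (t > longest_partial) longest_partial = t;
          continue;
        }
        int pick = (int)(rng.runif() * n_valid);
        if (pick >= n_valid) pick = n_valid - 1;
        double *dst = ch + (size_t)t * 3;
        for (int k = 0; k < 3; ++k) dst[k] = cand[(size_t)pick * 3 + k];
        lw[c] += std::log((double)n_valid) - std::log((double)n_cand);
      }

      bool at_checkpoint = (t % checkpoint_every == 0) || (t == n_bins - 1);
      int n_alive = 0;
      for (int c = 0; c < n_chains; ++c)
        if (!dead[c]) ++n_alive;
      if (n_alive == 0) {
        collapsed = true;
        break;
      }
      if (!resample || !at_checkpoint) continue;

      double mx = R_NegInf;
      for (int c = 0; c < n_chains; ++c)
        if (!dead[c] && lw[c] > mx) mx = lw[c];
      std::vector<double> w(n_chains, 0.0);
      double sw = 0.0, sw2 = 0.0;
      for (int c = 0; c < n_chains; ++c) {
        if (!dead[c]) w[c] = std::exp(lw[c] - mx);
        sw += w[c];
        sw2 += w[c] * w[c];
      }
      double ess = sw * sw / sw2;
      if (ess < n_chains / 2.0 || n_alive < n_chains) {
        std::vector<int> src;
        systematic_resample(w, n_chains, rng, src);
        std::vector<double> nc2((size_t)n_chains * (t + 1) * 3);
        for (int c = 0; c < n_chains; ++c) {
          const double *s = chain_ptr(src[c]);
          std::copy(s, s + (size_t)(t + 1) * 3,
                    nc2.data() + (size_t)c * (t + 1) * 3);
        }
        for (int c = 0; c < n_chains; ++c) {
          std::copy(nc2.data() + (size_t)c * (t + 1) * 3,
                    nc2.data() + (size_t)(c + 1) * (t + 1) * 3, chain_ptr(c));
          lw[c] = 0.0;
          dead[c] = false;
        }
      }
    }

    if (!collapsed) break;
    ++restarts;
    if (restarts > max_restarts) {
      success = false;
      break;
    }
  }

  NumericVector out((size_t)n_chains * n_bins * 3);
  // store as n_bins x 3 x n_chains for easy R slicing
  for (int c = 0; c < n_chains; ++c)
    for (int t = 0; t < n_bins; ++t)
      for (int k = 0; k < 3; ++k)
        out[t + (size_t)k * n_bins + (size_t)c * n_bins * 3] =
            coords[(size_t)c * n_bins * 3 + (size_t)t * 3 + k];
  out.attr("dim") = IntegerVector::create(n_bins, 3, n_chains);

  return List::create(
      _["coords"] = out, _["log_weights"] = NumericVector(lw.begin(), lw.end()),
      _["dead_ends"] = (double)dead_ends, _["chain_starts"] = (double)starts,
      _["restarts"] = restarts, _["longest_partial"] = longest_partial,
      _["success"] = success);
}

// Weighted contact frequency matrix: entry (i,j) is the weighted fraction of
// conformations with beads i,j within `threshold`. Diagonal is 1.
// [[Rcpp::export]]
NumericMatrix contact_frequency_cpp(NumericVector coords, NumericVector w,
                                    double threshold) {
  IntegerVector dm = coords.attr("dim");
  int n = dm[0], m = dm[2];
  double thr2 = threshold * threshold;
  NumericMatrix out(n, n);
  double tot = 0.0;
  for (int c = 0; c < m; ++c) tot += w[c];
  for (int c = 0; c < m; ++c) {
    const double *base = &coords[0] + (size_t)c * n * 3;
    for (int i = 0; i < n; ++i) {
      double xi = base[i], yi = base[i + n], zi = base[i + 2 * n];
      for (int j = i + 1; j < n; ++j) {
        double dx = xi - base[j], dy = yi - base[j + n],
               dz = zi - base[j + 2 * n];
        if (dx * dx + dy * dy + dz * dz <= thr2) out(i, j) += w[c];
      }
    }
  }
  for (int i = 0; i < n; ++i) {
    out(i, i) = 1.0;
    for (int j = i + 1; j < n; ++j) {
      out(i, j) /= tot;
      out(j, i) = out(i, j);
    }
  }
  return out;
}

// Weighted mean pairwise Euclidean distance matrix (nm).
// [[Rcpp::export]]
NumericMatrix mean_distance_cpp(NumericVector coords, NumericVector w) {
  IntegerVector dm = coords.attr("dim");
  int n = dm[0], m = dm[2];
  NumericMatrix out(n, n);
  double tot = 0.0;
  for (int c = 0; c < m; ++c) tot += w[c];
  for (int c = 0; c < m; ++c) {
    const double *base = &coords[0] + (size_t)c * n * 3;
    for (int i = 0; i < n; ++i) {
      double xi = base[i], yi = base[i + n], zi = base[i + 2 * n];
      for (int j = i + 1; j < n; ++j) {
        double dx = xi - base[j], dy = yi - base[j + n],
               dz = zi - base[j + 2 * n];
        out(i, j) += w[c] * std::sqrt(dx * dx + dy * dy + dz * dz);
      }
    }
  }
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      out(i, j) /= tot;
      out(j, i) = out(i, j);
    }
  return out;
}

// Per-chain, per-pair contact indicators (0/1). Rows: chains; columns: the
// upper-triangle pairs in column order (i < j), i.e. pair index of (i, j) is
// (j-1)(j-2)/2 + i with 1-based i, j. Used by the BLB null.
// [[Rcpp::export]]
IntegerMatrix pair_indicator_cpp(NumericVector coords, double threshold) {
  IntegerVector dm = coords.attr("dim");
  int n = dm[0], m = dm[2];
  double thr2 = threshold * threshold;
  IntegerMatrix out(m, n * (n - 1) / 2);
  for (int c = 0; c < m; ++c) {
    const double *base = &coords[0] + (size_t)c * n * 3;
    int col = 0;
    for (int j = 1; j < n; ++j) {
      for (int i = 0; i < j; ++i, ++col) {
        double dx = base[i] - base[j], dy = base[i + n] - base[j + n],
               dz = base[i + 2 * n] - base[j + 2 * n];
        if (dx * dx + dy * dy + dz * dz <= thr2) out(c, col) = 1;
      }
    }
  }
  return out;
}

// All triplets (1-based) of a single conformation with pairwise distance
// <= threshold and pairwise genomic separation >= min_sep. Bitset adjacency
// keeps enumeration near-linear in the number of triangles.
// [[Rcpp::export]]
IntegerMatrix triangles_cpp(NumericMatrix conf, double threshold,
                            int min_sep) {
  int n = conf.nrow();
  double thr2 = threshold * threshold;
  int W = (n + 63) / 64;
  std::vector<uint64_t> adj((size_t)n * W, 0);
  std::vector<std::pair<int, int>> edges;
  for (int i = 0; i < n; ++i)
    for (int j = i + min_sep; j < n; ++j) {
      double dx = conf(i, 0) - conf(j, 0), dy = conf(i, 1) - conf(j, 1),
             dz = conf(i, 2) - conf(j, 2);
      if (dx * dx + dy * dy + dz * dz <= thr2) {
        adj[(size_t)i * W + j / 64] |= (uint64_t)1 << (j % 64);
        adj[(size_t)j * W + i / 64] |= (uint64_t)1 << (i % 64);
        edges.emplace_back(i, j);
      }
    }
  std::vector<int> tri;
  for (auto &e : edges) {
    int i = e.first, j = e.second;
    int kmin = j + min_sep; // k > j ensures |k - i| >= min_sep too
    if (kmin >= n) continue;
    for (int w = kmin / 64; w < W; ++w) {
      uint64_t bits = adj[(size_t)i * W + w] & adj[(size_t)j * W + w];
      if (w == kmin / 64 && (kmin % 64) > 0)
        bits &= ~(((uint64_t)1 << (kmin % 64)) - 1);
      while (bits) {
        int b = __builtin_ctzll(bits);
        bits &= bits - 1;
        int k = w * 64 + b;
        tri.push_back(i + 1);
        tri.push_back(j + 1);
        tri.push_back(k + 1);
      }
    }
  }
  IntegerMatrix out(tri.size() / 3, 3);
  for (int r = 0; r < out.nrow(); ++r)
    for (int k = 0; k < 3; ++k) out(r, k) = tri[(size_t)r * 3 + k];
  return out;
}

// Edge list (1-based, i < j) of the contact graph of one conformation,
// restricted to pairs with genomic separation >= min_sep.
// [[Rcpp::export]]
IntegerMatrix contact_edges_cpp(NumericMatrix conf, double threshold,
                                int min_sep) {
  int n = conf.nrow();
  double thr2 = threshold * threshold;
  std::vector<int> e;
  for (int i = 0; i < n; ++i)
    for (int j = i + min_sep; j < n; ++j) {
      double dx = conf(i, 0) - conf(j, 0), dy = conf(i, 1) - conf(j, 1),
             dz = conf(i, 2) - conf(j, 2);
      if (dx * dx + dy * dy + dz * dz <= thr2) {
        e.push_back(i + 1);
        e.push_back(j + 1);
      }
    }
  IntegerMatrix out(e.size() / 2, 2);
  for (int r = 0; r < out.nrow(); ++r) {
    out(r, 0) = e[(size_t)r * 2];
    out(r, 1) = e[(size_t)r * 2 + 1];
  }
  return out;
}

namespace {
// BLB replicate machinery shared by the two bootstrap entry points: draw a
// weighted subset of b = ceil(n^gamma) chains without replacement
// (exponential keys), multinomially resample it to full size n.
struct BlbDraw {
  std::vector<int> idx;
  std::vector<double> mult;
};

void blb_replicate(int n, int b, const std::vector<double> &w, Rng &rng,
                   BlbDraw &out) {
  std::vector<std::pair<double, int>> keys(n);
  for (int i = 0; i < n; ++i) {
    double e = -std::log(rng.runif() + 1e-300) / (w[i] + 1e-300);
    keys[i] = {e, i};
  }
  std::partial_sort(keys.begin(), keys.begin() + b, keys.end());
  out.idx.resize(b);
  out.mult.assign(b, 0.0);
  double wtot = 0.0;
  for (int k = 0; k < b; ++k) {
    out.idx[k] = keys[k].second;
    wtot += w[keys[k].second];
  }
  // sequential conditional binomials == multinomial(n, w_subset)
  int remaining = n;
  double wrem = wtot;
  for (int k = 0; k < b && remaining > 0; ++k) {
    double p = w[out.idx[k]] / wrem;
    if (p > 1.0) p = 1.0;
    std::binomial_distribution<int> bin(remaining, p);
    int m = (k == b - 1) ? remaining : bin(rng.eng);
    out.mult[k] = m;
    remaining -= m;
    wrem -= w[out.idx[k]];
  }
}

std::vector<std::vector<int>> contact_lists(const IntegerMatrix &ind) {
  int n = ind.nrow(), P = ind.ncol();
  std::vector<std::vector<int>> cl(n);
  for (int i = 0; i < n; ++i)
    for (int p = 0; p < P; ++p)
      if (ind(i, p)) cl[i].push_back(p);
  return cl;
}
} // namespace

// Per-distance-stratum BLB collections: each replicate records the resampled
// contact frequency of one uniformly drawn pair at every genomic distance.
// Pair columns follow pair_indicator_cpp order.
// [[Rcpp::export]]
NumericMatrix blb_distance_reps_cpp(IntegerMatrix ind, NumericVector w,
                                    int n_bins, int n_outer, double gamma,
                                    double seed) {
  int n = ind.nrow();
  int b = std::max(2, (int)std::ceil(std::pow((double)n, gamma)));
  Rng rng((unsigned long)seed);
  std::vector<double> wv(w.begin(), w.end());
  auto cl = contact_lists(ind);
  int S = n_bins - 1;
  NumericMatrix out(n_outer, S);
  std::vector<double> acc(ind.ncol());
  BlbDraw draw;
  for (int r = 0; r < n_outer; ++r) {
    blb_replicate(n, b, wv, rng, draw);
    std::fill(acc.begin(), acc.end(), 0.0);
    for (size_t k = 0; k < draw.idx.size(); ++k) {
      double m = draw.mult[k];
      if (m == 0) continue;
      for (int p : cl[draw.idx[k]]) acc[p] += m;
    }
    for (int s = 1; s <= S; ++s) {
      int i = (int)(rng.runif() * (n_bins - s));
      if (i >= n_bins - s) i = n_bins - s - 1;
      int j = i + s;
      int col = j * (j - 1) / 2 + i; // 0-based (i, j) pair column
      out(r, s - 1) = acc[col] / n;
    }
  }
  return out;
}

// Same-pair BLB exceedance counts: for every pair, the number of bootstrap
// replicates whose resampled frequency of that pair reaches `measured`.
// [[Rcpp::export]]
NumericVector blb_exceed_cpp(IntegerMatrix ind, NumericVector w,
                             NumericVector measured, int n_outer,
                             double gamma, double seed) {
  int n = ind.nrow(), P = ind.ncol();
  int b = std::max(2, (int)std::ceil(std::pow((double)n, gamma)));
  Rng rng((unsigned long)seed);
  std::vector<double> wv(w.begin(), w.end());
  auto cl = contact_lists(ind);
  NumericVector exceed(P);
  std::vector<double> acc(P);
  BlbDraw draw;
  for (int r = 0; r < n_outer; ++r) {
    blb_replicate(n, b, wv, rng, draw);
    std::fill(acc.begin(), acc.end(), 0.0);
    for (size_t k = 0; k < draw.idx.size(); ++k) {
      double m = draw.mult[k];
      if (m == 0) continue;
      for (int p : cl[draw.idx[k]]) acc[p] += m;
    }
    for (int p = 0; p < P; ++p)
      if (acc[p] / n >= measured[p] - 1e-12) exceed[p] += 1.0;
  }
  return exceed;
}
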