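#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Linear-extension machinery for binding-dependency DAGs.
// Proteins are bits 0..n-1; pred[j] is the bitmask of prerequisites of j.
// All subset DP runs over downward-closed sets: f[S] (number of permitted
// prefixes realising S) is nonzero only when S is downward closed, because
// f[empty] = 1 and a protein is only appended when its prerequisites are
// already in S.

static inline int popcount32(uint32_t x) {
#ifdef __GNUC__
  return __builtin_popcount(x);
#else
  int c = 0; while (x) { x &= x - 1; ++c; } return c;
#endif
}

// [[Rcpp::export]]
double cpp_count_extensions(IntegerVector pred) {
  const int n = pred.size();
  const size_t full = (size_t(1) << n);
  std::vector<double> f(full, 0.0);
  f[0] = 1.0;
  for (size_t mask = 1; mask < full; ++mask) {
    double s = 0.0;
    for (int j = 0; j < n; ++j) {
      uint32_t bit = uint32_t(1) << j;
      if ((mask & bit) && ((uint32_t(pred[j]) & ~(uint32_t(mask) ^ bit)) == 0u))
        s += f[mask ^ bit];
    }
    f[mask] = s;
  }
  return f[full - 1];
}

static double enum_count_rec(const std::vector<uint32_t>& pred, uint32_t mask,
                             uint32_t fullmask, int n) {
  if (mask == fullmask) return 1.0;
  double s = 0.0;
  for (int j = 0; j < n; ++j) {
    uint32_t bit = uint32_t(1) << j;
    if (!(mask & bit) && (pred[j] & ~mask) == 0u)
      s += enum_count_rec(pred, mask | bit, fullmask, n);
  }
  return s;
}

// Exhaustive depth-first count; independent cross-check of the subset DP.
// [[Rcpp::export]]
double cpp_count_extensions_enum(IntegerVector pred) {
  const int n = pred.size();
  std::vector<uint32_t> p(n);
  for (int j = 0; j < n; ++j) p[j] = uint32_t(pred[j]);
  return enum_count_rec(p, 0u, (uint32_t(1) << n) - 1u, n);
}

static void enum_rec(const std::vector<uint32_t>& pred,
                     const std::vector<int>& prio, uint32_t mask,
                     std::vector<int>& cur, IntegerMatrix& out, R_xlen_t& row,
                     int n) {
  if ((int)cur.size() == n) {
    for (int k = 0; k < n; ++k) out(row, k) = cur[k] + 1;
    ++row;
    return;
  }
  for (int t = 0; t < n; ++t) {
    int j = prio[t];
    uint32_t bit = uint32_t(1) << j;
    if (!(mask & bit) && (pred[j] & ~mask) == 0u) {
      cur.push_back(j);
      enum_rec(pred, prio, mask | bit, cur, out, row, n);
      cur.pop_back();
    }
  }
}

// Enumerate all extensions; candidate proteins tried in the order given by
// `priority` (0-based), which fixes the emission order deterministically.
// [[Rcpp::export]]
IntegerMatrix cpp_enumerate_extensions(IntegerVector pred,
                                       IntegerVector priority,
                                       double total) {
  const int n = pred.size();
  std::vector<uint32_t> p(n);
  for (int j = 0; j < n; ++j) p[j] = uint32_t(pred[j]);
  std::vector<int> prio(priority.begin(), priority.end());
  IntegerMatrix out((R_xlen_t)total, n);
  R_xlen_t row = 0;
  std::vector<int> cur;
  cur.reserve(n);
  enum_rec(p, prio, 0u, cur, out, row, n);
  return out;
}

// Completion counts g[S] = number of permitted ways to finish an order whose
// prefix realises S.
static void completion_table(const std::vector<uint32_t>& pred,
                             std::vector<double>& g, int n) {
  const size_t full = g.size() - 1;
  g[full] = 1.0;
  for (size_t m = full; m-- > 0;) {
    double s = 0.0;
    for (int j = 0; j < n; ++j) {
      uint32_t bit = uint32_t(1) << j;
      if (!(m & bit) && (pred[j] & ~uint32_t(m)) == 0u) s += g[m | bit];
    }
    g[m] = s;
  }
}

// Exact position probabilities for the proteins in keep_mask, positions
// renumbered over kept proteins only (excluded proteins close ranks).
// Returns an (n_keep x n_keep) matrix, rows in bit order of keep_mask.
// [[Rcpp::export]]
NumericMatrix cpp_reo_exact(IntegerVector pred, int keep_mask) {
  const int n = pred.size();
  const size_t full = (size_t(1) << n);
  std::vector<uint32_t> p(n);
  for (int j = 0; j < n; ++j) p[j] = uint32_t(pred[j]);
  std::vector<double> f(full, 0.0), g(full, 0.0);
  f[0] = 1.0;
  for (size_t mask = 1; mask < full; ++mask) {
    double s = 0.0;
    for (int j = 0; j < n; ++j) {
      uint32_t bit = uint32_t(1) << j;
      if ((mask & bit) && ((p[j] & ~(uint32_t(mask) ^ bit)) == 0u))
        s += f[mask ^ bit];
    }
    f[mask] = s;
  }
  completion_table(p, g, n);
  const double total = f[full - 1];
  const uint32_t keep = uint32_t(keep_mask);
  const int nk = popcount32(keep);
  std::vector<int> keeprow(n, -1);
  int r = 0;
  for (int j = 0; j < n; ++j) if (keep & (uint32_t(1) << j)) keeprow[j] = r++;
  NumericMatrix P(nk, nk);
  for (size_t mask = 0; mask < full; ++mask) {
    if (f[mask] == 0.0) continue;
    for (int j = 0; j < n; ++j) {
      uint32_t bit = uint32_t(1) << j;
      if ((mask & bit) || (p[j] & ~uint32_t(mask)) != 0u) continue;
      if (keeprow[j] < 0) continue;
      int pos = popcount32(uint32_t(mask) & keep); // 0-based reduced position
      P(keeprow[j], pos) += f[mask] * g[mask | bit];
    }
  }
  for (int a = 0; a < nk; ++a)
    for (int b = 0; b < nk; ++b) P(a, b) /= total;
  return P;
}

// Sample linear extensions. uniform = true draws exactly uniformly over all
// extensions (sequential choice weighted by completion counts); otherwise
// the "frontier" heuristic picks uniformly among currently bindable
// proteins. Uses R's RNG stream.
// [[Rcpp::export]]
IntegerMatrix cpp_sample_extensions(IntegerVector pred, int nsamp,
                                    bool uniform) {
  const int n = pred.size();
  const size_t full = (size_t(1) << n);
  std::vector<uint32_t> p(n);
  for (int j = 0; j < n; ++j) p[j] = uint32_t(pred[j]);
  std::vector<double> g;
  if (uniform) {
    g.assign(full, 0.0);
    completion_table(p, g, n);
    if (g[0] == 0.0) stop("rule set admits no permitted order");
  }
  IntegerMatrix out(nsamp, n);
  std::vector<int> frontier(n);
  for (int s = 0; s < nsamp; ++s) {
    uint32_t mask = 0u;
    for (int k = 0; k < n; ++k) {
      int nf = 0;
      for (int j = 0; j < n; ++j) {
        uint32_t bit = uint32_t(1) << j;
        if (!(mask & bit) && (p[j] & ~mask) == 0u) frontier[nf++] = j;
      }
      int pick;
      if (uniform) {
        double tot = 0.0;
        for (int t = 0; t < nf; ++t)
          tot += g[mask | (uint32_t(1) << frontier[t])];
        double u = unif_rand() * tot, acc = 0.0;
        pick = frontier[nf - 1];
        for (int t = 0; t < nf; ++t) {
          acc += g[mask | (uint32_t(1) << frontier[t])];
          if (u <= acc) { pick = frontier[t]; break; }
        }
      } else {
        int t = (int)(unif_rand() * nf);
        if (t >= nf) t = nf - 1;
        pick = frontier[t];
      }
      out(s, k) = pick + 1;
      mask |= uint32_t(1) << pick;
    }
  }
  return out;
}

// ---- constrained monotone random walks over a residual matrix ----
//
// A walk starts uniformly on the first row or first column (corner counted
// once), moves by down / right / diagonal steps, never takes a right step
// immediately after a down step nor a down step immediately after a right
// step, and terminates on first arrival in the last row or last column.
// Score = mean of visited entries.

struct WalkSink {
  virtual void cell(int i, int j) = 0;
  virtual ~WalkSink() {}
};

static double run_one_walk(const NumericMatrix& mat, WalkSink* sink) {
  const int m = mat.nrow(), n = mat.ncol();
  int nstarts = m + n - 1;
  int s = (int)(unif_rand() * nstarts);
  if (s >= nstarts) s = nstarts - 1;
  int i, j;
  if (s < n) { i = 0; j = s; } else { i = s - n + 1; j = 0; }
  double total = mat(i, j);
  int len = 1;
  if (sink) sink->cell(i, j);
  int prev = 0; // 0 none, 1 down, 2 right, 3 diag
  while (i < m - 1 && j < n - 1) {
    int moves[3], nm = 0;
    if (prev != 2) moves[nm++] = 1; // down allowed unless preceded by right
    if (prev != 1) moves[nm++] = 2; // right allowed unless preceded by down
    moves[nm++] = 3;               // diagonal always allowed
    int t = (int)(unif_rand() * nm);
    if (t >= nm) t = nm - 1;
    int mv = moves[t];
    if (mv == 1) ++i;
    else if (mv == 2) ++j;
    else { ++i; ++j; }
    prev = mv;
    total += mat(i, j);
    ++len;
    if (sink) sink->cell(i, j);
  }
  return total / len;
}

// [[Rcpp::export]]
NumericVector cpp_walk_scores(NumericMatrix mat, int n_walks) {
  NumericVector scores(n_walks);
  for (int w = 0; w < n_walks; ++w) scores[w] = run_one_walk(mat, nullptr);
  return scores;
}

struct FreqSink : public WalkSink {
  NumericMatrix* freq;
  bool active;
  std::vector<int> track_i, track_j;
  bool tracking;
  FreqSink() : freq(nullptr), active(false), tracking(false) {}
  void cell(int i, int j) {
    if (active && freq) (*freq)(i, j) += 1.0;
    if (tracking) { track_i.push_back(i); track_j.push_back(j); }
  }
};

// Replays the identical RNG stream as cpp_walk_scores (same seed => same
// walks); accumulates per-cell coverage over walks flagged in `selected`
// and records the cells of walk `track_index` (1-based, 0 = none).
// [[Rcpp::export]]
List cpp_walk_collect(NumericMatrix mat, int n_walks, LogicalVector selected,
                      int track_index) {
  NumericMatrix freq(mat.nrow(), mat.ncol());
  FreqSink sink;
  sink.freq = &freq;
  double nsel = 0.0;
  for (int w = 0; w < n_walks; ++w) {
    sink.active = (w < selected.size()) && selected[w];
    sink.tracking = (w + 1 == track_index);
    if (sink.active) nsel += 1.0;
    run_one_walk(mat, &sink);
  }
  if (nsel > 0)
    for (int a = 0; a < freq.nrow(); ++a)
      for (int b = 0; b < freq.ncol(); ++b) freq(a, b) /= nsel;
  IntegerMatrix cells(sink.track_i.size(), 2);
  for (size_t k = 0; k < sink.track_i.size(); ++k) {
    cells(k, 0) = sink.track_i[k] + 1;
    cells(k, 1) = sink.track_j[k] + 1;
  }
  return List::create(_["freq"] = freq, _["cells"] = cells);
}
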