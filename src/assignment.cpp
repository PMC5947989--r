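// Dense linear sum assignment (Jonker-Volgenant shortest augmenting path)
// and the movie-level minimal-displacement distance used by the spatial
// coherence metric.
//
// The movie distance exploits two structural facts about coarse looming
// movies: (i) pixel luminance is non-increasing in time, so the set of fully
// dark pixels only grows and its assignment problem can be solved
// incrementally by augmenting the new rows against warm-started duals;
// (ii) jitter preserves each pixel's luminance time course, so the
// equal-luminance groups are identical pixel-id sets in the jittered and
// reference movies.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
#include <algorithm>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// Shortest augmenting path for one unassigned row `curRow`.
// cost(i,j) is supplied via a functor. Maintains dual feasibility:
// c_ij - u_i - v_j >= 0 for all assigned rows i, with equality on matched
// pairs. Standard algorithm (as used by scipy's linear_sum_assignment).
template <class COST>
static void augment_row(int n, int curRow, const COST& cost,
                        std::vector<double>& u, std::vector<double>& v,
                        std::vector<int>& col4row, std::vector<int>& row4col,
                        std::vector<double>& shortest, std::vector<int>& path,
                        std::vector<char>& SR, std::vector<char>& SC,
                        std::vector<int>& remaining) {
  double minVal = 0.0;
  int i = curRow;
  int num_remaining = n;
  for (int it = 0; it < n; ++it) remaining[it] = n - it - 1;
  std::fill(SR.begin(), SR.end(), 0);
  std::fill(SC.begin(), SC.end(), 0);
  std::fill(shortest.begin(), shortest.end(), INF);

  int sink = -1;
  while (sink == -1) {
    int index = -1;
    double lowest = INF;
    SR[i] = 1;
    for (int it = 0; it < num_remaining; ++it) {
      int j = remaining[it];
      double r = minVal + cost(i, j) - u[i] - v[j];
      if (r < shortest[j]) { path[j] = i; shortest[j] = r; }
      if (shortest[j] < lowest ||
          (shortest[j] == lowest && row4col[j] == -1)) {
        lowest = shortest[j];
        index = it;
      }
    }
    minVal = lowest;
    if (!(minVal < INF)) stop("assignment problem is infeasible");
    int j = remaining[index];
    if (row4col[j] == -1) sink = j; else i = row4col[j];
    SC[j] = 1;
    remaining[index] = remaining[--num_remaining];
  }

  u[curRow] += minVal;
  for (int ii = 0; ii < (int)u.size(); ++ii)
    if (SR[ii] && ii != curRow) u[ii] += minVal - shortest[col4row[ii]];
  for (int jj = 0; jj < n; ++jj)
    if (SC[jj]) v[jj] -= minVal - shortest[jj];

  int j = sink;
  while (true) {
    int ii = path[j];
    row4col[j] = ii;
    std::swap(col4row[ii], j);
    if (ii == curRow) break;
  }
}

struct MatCost {
  const NumericMatrix& m;
  double operator()(int i, int j) const { return m(i, j); }
};

// [[Rcpp::export]]
List lapjv_cpp(NumericMatrix cost) {
  int n = cost.nrow();
  if (cost.ncol() != n) stop("cost matrix must be square");
  if (n == 0) return List::create(_["assignment"] = IntegerVector(0),
                                  _["cost"] = 0.0);
  std::vector<double> u(n, 0.0), v(n, 0.0), shortest(n);
  std::vector<int> col4row(n, -1), row4col(n, -1), path(n, -1), remaining(n);
  std::vector<char> SR(n), SC(n);
  MatCost c{cost};
  for (int r = 0; r < n; ++r)
    augment_row(n, r, c, u, v, col4row, row4col, shortest, path, SR, SC,
                remaining);
  double total = 0.0;
  IntegerVector assign(n);
  for (int i = 0; i < n; ++i) {
    assign[i] = col4row[i] + 1;
    total += cost(i, col4row[i]);
  }
  return List::create(_["assignment"] = assign, _["cost"] = total);
}

// ---------------------------------------------------------------------------
// Incremental solver for the growing "fully dark" group.

struct DarkSolver {
  // ids are dense local indices in order of addition; rows are jittered
  // positions, cols reference positions of the same pixel ids.
  std::vector<double> jx, jy, rx, ry;  // positions per local index
  std::vector<double> u, v;
  std::vector<int> col4row, row4col;
  int n = 0;

  double cost(int i, int j) const {
    double dx = jx[i] - rx[j], dy = jy[i] - ry[j];
    return std::sqrt(dx * dx + dy * dy);
  }

  // Add k new pixels (appended to both sides), re-optimize.
  void add(const std::vector<double>& njx, const std::vector<double>& njy,
           const std::vector<double>& nrx, const std::vector<double>& nry) {
    int k = (int)njx.size();
    if (k == 0) return;
    int n_old = n;
    for (int t = 0; t < k; ++t) {
      jx.push_back(njx[t]); jy.push_back(njy[t]);
      rx.push_back(nrx[t]); ry.push_back(nry[t]);
    }
    n += k;
    u.resize(n, 0.0);
    col4row.resize(n, -1);
    row4col.resize(n, -1);
    // New columns: duals preserving c_ij - u_i - v_j >= 0 for every row.
    v.resize(n);
    for (int j = n_old; j < n; ++j) {
      double vj = INF;
      for (int i = 0; i < n; ++i) {
        double r = cost(i, j) - u[i];
        if (r < vj) vj = r;
      }
      v[j] = vj;
    }
    std::vector<double> shortest(n);
    std::vector<int> path(n, -1), remaining(n);
    std::vector<char> SR(n), SC(n);
    struct SelfCost {
      const DarkSolver* s;
      double operator()(int i, int j) const { return s->cost(i, j); }
    } c{this};
    for (int r = n_old; r < n; ++r)
      augment_row(n, r, c, u, v, col4row, row4col, shortest, path, SR, SC,
                  remaining);
  }

  double total() const {
    double tot = 0.0;
    for (int i = 0; i < n; ++i) tot += cost(i, col4row[i]);
    return tot;
  }
};

// Solve a small group's assignment from scratch (positions of same ids).
static double group_cost(const std::vector<int>& ids,
                         const NumericMatrix& jpos, const NumericMatrix& rpos,
                         std::vector<double>& u, std::vector<double>& v,
                         std::vector<double>& shortest, std::vector<int>& path,
                         std::vector<int>& col4row, std::vector<int>& row4col,
                         std::vector<char>& SR, std::vector<char>& SC,
                         std::vector<int>& remaining) {
  int n = (int)ids.size();
  if (n == 0) return 0.0;
  if (n == 1) {
    double dx = jpos(ids[0], 0) - rpos(ids[0], 0);
    double dy = jpos(ids[0], 1) - rpos(ids[0], 1);
    return std::sqrt(dx * dx + dy * dy);
  }
  // multiset-equality shortcut: identical position sets match at zero cost
  {
    std::vector<std::pair<double, double>> a(n), b(n);
    for (int t = 0; t < n; ++t) {
      a[t] = {jpos(ids[t], 0), jpos(ids[t], 1)};
      b[t] = {rpos(ids[t], 0), rpos(ids[t], 1)};
    }
    std::sort(a.begin(), a.end());
    std::sort(b.begin(), b.end());
    if (a == b) return 0.0;
  }
  u.assign(n, 0.0); v.assign(n, 0.0);
  col4row.assign(n, -1); row4col.assign(n, -1);
  shortest.resize(n); path.resize(n); remaining.resize(n);
  SR.resize(n); SC.resize(n);
  struct GCost {
    const std::vector<int>& ids;
    const NumericMatrix& jp;
    const NumericMatrix& rp;
    double operator()(int i, int j) const {
      double dx = jp(ids[i], 0) - rp(ids[j], 0);
      double dy = jp(ids[i], 1) - rp(ids[j], 1);
      return std::sqrt(dx * dx + dy * dy);
    }
  } c{ids, jpos, rpos};
  for (int r = 0; r < n; ++r)
    augment_row(n, r, c, u, v, col4row, row4col, shortest, path, SR, SC,
                remaining);
  double tot = 0.0;
  for (int i = 0; i < n; ++i) tot += c(i, col4row[i]);
  return tot;
}

// Total minimal angular displacement between a jittered and a reference
// movie, summed over frames. lum: n_pixels x n_frames integer luminance,
// shared by both movies (jitter leaves time courses unchanged). Pixels at
// background level are excluded; within a frame, pixels are matched within
// equal-luminance groups. Positions are screen coordinates in degrees.
// [[Rcpp::export]]
List movie_distance_cpp(NumericMatrix jit_pos, NumericMatrix ref_pos,
                        IntegerMatrix lum, int background, int dark) {
  int n_pix = lum.nrow(), n_frames = lum.ncol();
  if (jit_pos.nrow() != n_pix || ref_pos.nrow() != n_pix)
    stop("position matrices must have one row per pixel");
  NumericVector per_frame(n_frames);

  // Identical layouts: every frame reconstitutes at zero cost.
  bool identical_layout = true;
  for (int i = 0; i < n_pix && identical_layout; ++i)
    if (jit_pos(i, 0) != ref_pos(i, 0) || jit_pos(i, 1) != ref_pos(i, 1))
      identical_layout = false;
  if (identical_layout)
    return List::create(_["total"] = 0.0, _["per_frame"] = per_frame);

  DarkSolver darksolver;
  std::vector<char> in_dark(n_pix, 0);
  std::vector<double> u, v, shortest;
  std::vector<int> path, col4row, row4col, remaining;
  std::vector<char> SR, SC;

  double total = 0.0;
  double prev_frame_cost = 0.0;
  bool have_prev = false;

  std::vector<int> order(n_pix);
  std::vector<std::vector<int>> groups;

  for (int f = 0; f < n_frames; ++f) {
    // unchanged frame (e.g. frozen at maximal size): reuse previous cost
    if (have_prev) {
      bool same = true;
      for (int i = 0; i < n_pix; ++i)
        if (lum(i, f) != lum(i, f - 1)) { same = false; break; }
      if (same) {
        per_frame[f] = prev_frame_cost;
        total += prev_frame_cost;
        continue;
      }
    }

    // grow the dark set
    std::vector<double> njx, njy, nrx, nry;
    for (int i = 0; i < n_pix; ++i) {
      if (!in_dark[i] && lum(i, f) == dark && dark != background) {
        in_dark[i] = 1;
        njx.push_back(jit_pos(i, 0)); njy.push_back(jit_pos(i, 1));
        nrx.push_back(ref_pos(i, 0)); nry.push_back(ref_pos(i, 1));
      }
    }
    darksolver.add(njx, njy, nrx, nry);
    double fcost = darksolver.total();

    // group remaining non-background pixels by luminance level
    groups.clear();
    {
      std::vector<std::pair<int, int>> lv;  // (level, pixel)
      for (int i = 0; i < n_pix; ++i) {
        int L = lum(i, f);
        if (L != background && !(L == dark && in_dark[i]))
          lv.push_back({L, i});
      }
      std::sort(lv.begin(), lv.end());
      size_t a = 0;
      while (a < lv.size()) {
        size_t b = a;
        std::vector<int> g;
        while (b < lv.size() && lv[b].first == lv[a].first) {
          g.push_back(lv[b].second);
          ++b;
        }
        groups.push_back(std::move(g));
        a = b;
      }
    }
    for (auto& g : groups)
      fcost += group_cost(g, jit_pos, ref_pos, u, v, shortest, path, col4row,
                          row4col, SR, SC, remaining);

    per_frame[f] = fcost;
    total += fcost;
    prev_frame_cost = fcost;
    have_prev = true;
  }
  return List::create(_["total"] = total, _["per_frame"] = per_frame);
}
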