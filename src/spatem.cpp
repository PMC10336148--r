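#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
#include <functional>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// k-nearest neighbours (brute force; point sets here are a few thousand cells)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_knn(NumericMatrix pts, NumericMatrix query, int k, bool exclude_self) {
  int n = pts.nrow(), m = query.nrow(), p = pts.ncol();
  IntegerMatrix out(m, k);
  NumericMatrix dist(m, k);
  std::vector<std::pair<double,int> > d(n);
  for (int q = 0; q < m; ++q) {
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int c = 0; c < p; ++c) {
        double dd = pts(i, c) - query(q, c);
        s += dd * dd;
      }
      d[i] = std::make_pair(s, i);
    }
    int kk = std::min(k + (exclude_self ? 1 : 0), n);
    std::partial_sort(d.begin(), d.begin() + kk, d.end());
    int col = 0;
    for (int i = 0; i < kk && col < k; ++i) {
      if (exclude_self && d[i].second == q) continue;
      out(q, col) = d[i].second + 1;   // 1-based
      dist(q, col) = std::sqrt(d[i].first);
      ++col;
    }
    for (; col < k; ++col) { out(q, col) = NA_INTEGER; dist(q, col) = NA_REAL; }
  }
  return List::create(_["index"] = out, _["dist"] = dist);
}

// ---------------------------------------------------------------------------
// Neighbourhood-composition permutation enrichment
// neigh: n x k matrix of 1-based neighbour indices; labels: 1..L
// Returns observed fraction (L x L, query x target), permutation mean and
// the count of permutations with fraction >= observed.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_knn_enrichment(IntegerMatrix neigh, IntegerVector labels, int n_classes,
                        int n_perm) {
  int n = neigh.nrow(), k = neigh.ncol();
  NumericMatrix obs(n_classes, n_classes), perm_sum(n_classes, n_classes);
  IntegerMatrix ge(n_classes, n_classes);
  std::vector<int> lab(n);
  for (int i = 0; i < n; ++i) lab[i] = labels[i] - 1;
  std::vector<double> denom(n_classes, 0.0);

  std::vector<double> cnt(n_classes * n_classes);
  auto tally = [&](const std::vector<int>& L, NumericMatrix& dest) {
    std::fill(cnt.begin(), cnt.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      int q = L[i];
      for (int j = 0; j < k; ++j) {
        int nb = neigh(i, j);
        if (nb == NA_INTEGER) continue;
        cnt[q * n_classes + L[nb - 1]] += 1.0;
      }
    }
    for (int q = 0; q < n_classes; ++q) {
      double tot = 0.0;
      for (int t = 0; t < n_classes; ++t) tot += cnt[q * n_classes + t];
      for (int t = 0; t < n_classes; ++t)
        dest(q, t) = tot > 0 ? cnt[q * n_classes + t] / tot : NA_REAL;
    }
  };

  tally(lab, obs);

  std::vector<int> plab(n);
  NumericMatrix pf(n_classes, n_classes);
  for (int p = 0; p < n_perm; ++p) {
    IntegerVector idx = Rcpp::sample(n, n, false);   // uses R's RNG
    for (int i = 0; i < n; ++i) plab[i] = lab[idx[i] - 1];
    tally(plab, pf);
    for (int q = 0; q < n_classes; ++q)
      for (int t = 0; t < n_classes; ++t) {
        perm_sum(q, t) += pf(q, t);
        if (pf(q, t) >= obs(q, t)) ge(q, t) += 1;
      }
  }
  NumericMatrix perm_mean(n_classes, n_classes);
  for (int q = 0; q < n_classes; ++q)
    for (int t = 0; t < n_classes; ++t) perm_mean(q, t) = perm_sum(q, t) / n_perm;
  (void)denom;
  return List::create(_["observed"] = obs, _["perm_mean"] = perm_mean,
                      _["n_ge"] = ge);
}

// ---------------------------------------------------------------------------
// Cross-type Ripley's K in a polygonal window.
// Edge correction: isotropic (arc fraction inside window, evaluated by
// sampling n_arc points on the circle against a fine raster of the window),
// symmetrised over the two pair members so K_ab == K_ba exactly.
// ---------------------------------------------------------------------------

static inline bool raster_inside(const LogicalMatrix& mask, double x0, double y0,
                                 double cs, double x, double y) {
  int cx = (int)std::floor((x - x0) / cs);
  int cy = (int)std::floor((y - y0) / cs);
  if (cx < 0 || cy < 0 || cx >= mask.nrow() || cy >= mask.ncol()) return false;
  return mask(cx, cy);
}

// [[Rcpp::export]]
NumericMatrix cpp_pair_weights(NumericMatrix pts, LogicalMatrix mask,
                               double x0, double y0, double cs,
                               int n_arc, double w_cap) {
  int n = pts.nrow();
  NumericMatrix W(n, n);
  std::vector<double> ca(n_arc), sa(n_arc);
  for (int a = 0; a < n_arc; ++a) {
    double th = 2.0 * M_PI * (a + 0.5) / n_arc;
    ca[a] = std::cos(th); sa[a] = std::sin(th);
  }
  for (int i = 0; i < n; ++i) {
    W(i, i) = 0.0;
    for (int j = i + 1; j < n; ++j) {
      double dx = pts(j,0) - pts(i,0), dy = pts(j,1) - pts(i,1);
      double d = std::sqrt(dx*dx + dy*dy);
      int in_i = 0, in_j = 0;
      for (int a = 0; a < n_arc; ++a) {
        if (raster_inside(mask, x0, y0, cs, pts(i,0) + d*ca[a], pts(i,1) + d*sa[a])) ++in_i;
        if (raster_inside(mask, x0, y0, cs, pts(j,0) + d*ca[a], pts(j,1) + d*sa[a])) ++in_j;
      }
      double pi_ = std::max(in_i, 1) / (double)n_arc;
      double pj_ = std::max(in_j, 1) / (double)n_arc;
      double w = 0.5 * (1.0 / pi_ + 1.0 / pj_);
      if (w > w_cap) w = w_cap;
      W(i, j) = w; W(j, i) = w;
    }
  }
  return W;
}

// K_ab(r) for observed labels and n_perm random relabellings of the pooled
// two-class point set. lab: 1 = class a, 2 = class b (pooled points only).
// [[Rcpp::export]]
List cpp_cross_k(NumericMatrix D, NumericMatrix W, IntegerVector lab,
                 NumericVector radii, int n_perm, double area) {
  int n = D.nrow(), nr = radii.size();
  std::vector<int> L(n);
  for (int i = 0; i < n; ++i) L[i] = lab[i];

  auto kfun = [&](const std::vector<int>& lv, NumericVector out) {
    int na = 0, nb = 0;
    for (int i = 0; i < n; ++i) { if (lv[i] == 1) ++na; else ++nb; }
    std::vector<double> acc(nr, 0.0);
    for (int i = 0; i < n; ++i) {
      if (lv[i] != 1) continue;
      for (int j = 0; j < n; ++j) {
        if (lv[j] != 2) continue;
        double d = D(i, j);
        // cumulative: add weight to all radii >= d
        int lo = std::lower_bound(radii.begin(), radii.end(), d) - radii.begin();
        if (lo < nr) acc[lo] += W(i, j);
      }
    }
    double c = area / ((double)na * (double)nb);
    double run = 0.0;
    for (int r = 0; r < nr; ++r) { run += acc[r]; out[r] = c * run; }
  };

  NumericVector K_obs(nr);
  kfun(L, K_obs);

  NumericMatrix K_perm(n_perm, nr);
  std::vector<int> pl(n);
  NumericVector row(nr);
  for (int p = 0; p < n_perm; ++p) {
    IntegerVector idx = Rcpp::sample(n, n, false);
    for (int i = 0; i < n; ++i) pl[i] = L[idx[i] - 1];
    kfun(pl, row);
    for (int r = 0; r < nr; ++r) K_perm(p, r) = row[r];
  }
  return List::create(_["K_obs"] = K_obs, _["K_perm"] = K_perm);
}

// ---------------------------------------------------------------------------
// Exact Earth Mover's Distance: dense transportation simplex.
// Supplies a (m), demands b (n), cost c (m x n); sum(a) == sum(b).
// Basis kept as a spanning tree on the bipartite node set; entering arc by
// blocked Dantzig search; tiny supply perturbation guards against cycling.
// ---------------------------------------------------------------------------

struct Arc { int i, j; double flow; };

// [[Rcpp::export]]
List cpp_emd(NumericVector a_in, NumericVector b_in, NumericMatrix cost,
             int max_iter) {
  int m = a_in.size(), n = b_in.size();
  std::vector<double> a(a_in.begin(), a_in.end()), b(b_in.begin(), b_in.end());
  // perturbation for nondegeneracy
  double tot = 0.0; for (double v : a) tot += v;
  double delta = 1e-13 * tot / m;
  double extra = 0.0;
  for (int i = 0; i < m; ++i) { a[i] += delta * (i + 1); extra += delta * (i + 1); }
  b[n - 1] += extra;

  int nn = m + n;                       // node count; node id j -> m + j
  std::vector<Arc> basis; basis.reserve(nn);
  // row-greedy minimum-cost start: each allocation saturates exactly one
  // side (perturbed data), so the support is a spanning tree of m+n-1 arcs
  {
    std::vector<double> ra(a), rb(b);
    std::vector<char> open(n, 1);
    int n_open = n;
    for (int i = 0; i < m; ++i) {
      while (ra[i] > 0 && n_open > 0) {
        int bj = -1; double bc = 1e300;
        for (int j = 0; j < n; ++j) {
          if (open[j] && cost(i, j) < bc) { bc = cost(i, j); bj = j; }
        }
        if (bj < 0) break;
        double f = std::min(ra[i], rb[bj]);
        basis.push_back({i, bj, f});
        ra[i] -= f; rb[bj] -= f;
        if (rb[bj] <= 0 && !(i == m - 1 && ra[i] <= 0 && n_open == 1)) {
          open[bj] = 0; --n_open;
        }
        if (ra[i] <= 0) break;
      }
    }
  }
  // connectivity repair (exact ties can leave a forest): union-find over
  // nodes, then link stray components to node 0 with zero-flow arcs
  {
    std::vector<int> parent(nn);
    for (int x = 0; x < nn; ++x) parent[x] = x;
    std::function<int(int)> find = [&](int x) {
      while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
      return x;
    };
    for (const Arc& A : basis) {
      int ru = find(A.i), rv = find(m + A.j);
      if (ru != rv) parent[ru] = rv;
    }
    for (int x = 1; x < nn; ++x) {
      int rx = find(x), r0 = find(0);
      if (rx == r0) continue;
      if (x < m) basis.push_back({x, 0, 0.0});
      else       basis.push_back({0, x - m, 0.0});
      parent[rx] = r0;
    }
  }
  // adjacency: node -> list of basis arc indices
  std::vector<std::vector<int> > adj(nn);
  for (int e = 0; e < (int)basis.size(); ++e) {
    adj[basis[e].i].push_back(e);
    adj[m + basis[e].j].push_back(e);
  }

  std::vector<double> u(m), v(n);
  std::vector<int> par_node(nn), par_arc(nn);
  std::vector<char> seen(nn);
  std::vector<int> comp; comp.reserve(nn);

  const double* C = &cost(0, 0);            // column-major: C[i + (size_t)j*m]
  auto cst = [&](int i, int j) -> double { return C[i + (size_t)j * m]; };

  double cmax = 0.0;
  for (size_t e = 0; e < (size_t)m * n; ++e) cmax = std::max(cmax, std::fabs(C[e]));
  double tol = 1e-11 * std::max(1.0, cmax);

  // full dual computation (once; afterwards potentials update incrementally)
  {
    std::fill(seen.begin(), seen.end(), 0);
    std::queue<int> q; q.push(0); seen[0] = 1; u[0] = 0.0;
    while (!q.empty()) {
      int x = q.front(); q.pop();
      for (int e : adj[x]) {
        const Arc& A = basis[e];
        int y = (x == A.i) ? m + A.j : A.i;
        if (seen[y]) continue;
        seen[y] = 1;
        if (y >= m) v[y - m] = cst(A.i, A.j) - u[A.i];
        else        u[y]     = cst(A.i, A.j) - v[A.j];
        q.push(y);
      }
    }
  }

  // rooted-tree bookkeeping: parent pointers from node 0, cycles via LCA
  std::vector<int> stamp(nn, 0);
  int stamp_ctr = 0;
  {
    std::fill(seen.begin(), seen.end(), 0);
    std::queue<int> q; q.push(0); seen[0] = 1;
    par_node[0] = -1; par_arc[0] = -1;
    while (!q.empty()) {
      int x = q.front(); q.pop();
      for (int e : adj[x]) {
        const Arc& A = basis[e];
        int y = (x == A.i) ? m + A.j : A.i;
        if (seen[y]) continue;
        seen[y] = 1; par_node[y] = x; par_arc[y] = e;
        q.push(y);
      }
    }
  }

  long total_arcs = (long)m * n;
  long block = std::max(64L, (long)std::sqrt((double)total_arcs));
  long scan_pos = 0;
  int iter = 0;
  std::vector<int> chain_b, chain_t;      // arc ids up to the LCA
  while (iter++ < max_iter) {
    // blocked search for most negative reduced cost (j-major scan so memory
    // access is sequential in the column-major cost matrix)
    int bi = -1, bj = -1; double best = -tol;
    long scanned = 0;
    while (scanned < total_arcs) {
      long stop = std::min(block, total_arcs - scanned);
      for (long s2 = 0; s2 < stop; ++s2) {
        long e = scan_pos + scanned + s2;
        if (e >= total_arcs) e -= total_arcs;
        int j = (int)(e / m), i = (int)(e % m);
        double rc = C[e] - u[i] - v[j];
        if (rc < best) { best = rc; bi = i; bj = j; }
      }
      scanned += stop;
      if (bi >= 0) break;
    }
    scan_pos += scanned;
    if (scan_pos >= total_arcs) scan_pos -= total_arcs;
    if (bi < 0) break;                       // optimal
    int target = m + bj;

    // tree path between bi and target via lowest common ancestor
    ++stamp_ctr;
    for (int x = bi; x >= 0; x = par_node[x]) stamp[x] = stamp_ctr;
    int lca = target;
    while (stamp[lca] != stamp_ctr) lca = par_node[lca];
    chain_b.clear(); chain_t.clear();
    for (int x = bi; x != lca; x = par_node[x]) chain_b.push_back(par_arc[x]);
    for (int x = target; x != lca; x = par_node[x]) chain_t.push_back(par_arc[x]);
    // cycle arc order starting after the entering arc: target -> lca -> bi;
    // signs alternate -,+,-,... (entering arc itself is +)
    std::vector<int> path(chain_t);
    for (int s2 = (int)chain_b.size() - 1; s2 >= 0; --s2) path.push_back(chain_b[s2]);

    double theta = 1e300; int leave = -1; size_t leave_pos = 0;
    for (size_t s2 = 0; s2 < path.size(); s2 += 2) {
      if (basis[path[s2]].flow < theta) { theta = basis[path[s2]].flow; leave = path[s2]; leave_pos = s2; }
    }
    for (size_t s2 = 0; s2 < path.size(); ++s2) {
      if (s2 % 2 == 0) basis[path[s2]].flow -= theta;
      else             basis[path[s2]].flow += theta;
    }
    bool leave_on_target_side = leave_pos < chain_t.size();

    // remove leaving arc from adjacency
    {
      Arc& Lv = basis[leave];
      auto rm = [&](int node, int e) {
        auto& vec = adj[node];
        vec.erase(std::find(vec.begin(), vec.end(), e));
      };
      rm(Lv.i, leave); rm(m + Lv.j, leave);
    }

    // dual update: shift the smaller cut component (gauge freedom makes
    // either side valid); bidirectional BFS over the cut tree
    {
      std::vector<int> compA, compB;
      ++stamp_ctr;
      std::queue<int> qa, qb;
      qa.push(bi); stamp[bi] = stamp_ctr; compA.push_back(bi);
      qb.push(target); stamp[target] = stamp_ctr; compB.push_back(target);
      int done = 0;
      while (!done) {
        for (int side = 0; side < 2 && !done; ++side) {
          std::queue<int>& q2 = side == 0 ? qa : qb;
          std::vector<int>& cc = side == 0 ? compA : compB;
          if (q2.empty()) { done = side + 1; break; }
          int x = q2.front(); q2.pop();
          for (int e : adj[x]) {
            const Arc& A = basis[e];
            int y = (x == A.i) ? m + A.j : A.i;
            if (stamp[y] != stamp_ctr) { stamp[y] = stamp_ctr; q2.push(y); cc.push_back(y); }
          }
        }
      }
      if (done == 1) {
        for (int x : compA) { if (x < m) u[x] += best; else v[x - m] -= best; }
      } else {
        for (int x : compB) { if (x < m) u[x] -= best; else v[x - m] += best; }
      }
    }

    // install entering arc and re-root the cut subtree along the reversed
    // parent chain (the side holding the cut child reattaches through the
    // entering arc)
    basis[leave] = {bi, bj, theta};
    adj[bi].push_back(leave); adj[m + bj].push_back(leave);
    {
      int start = leave_on_target_side ? target : bi;
      int pnode = leave_on_target_side ? bi : target;
      int pa = leave;
      int cur = start;
      while (true) {
        int old_p = par_node[cur]; int old_a = par_arc[cur];
        par_node[cur] = pnode; par_arc[cur] = pa;
        if (old_a == leave || old_a < 0) break;   // reached the cut point
        pnode = cur; pa = old_a; cur = old_p;
      }
    }
  }

  double total_cost = 0.0;
  for (const Arc& A : basis) total_cost += A.flow * cost(A.i, A.j);
  bool converged = iter < max_iter;
  return List::create(_["cost"] = total_cost, _["iter"] = iter,
                      _["converged"] = converged);
}

// ---------------------------------------------------------------------------
// Entropic (Sinkhorn) approximation, used for very large grids.
// ---------------------------------------------------------------------------

// Log-domain (stabilized) Sinkhorn: dual potentials f, g updated by
// soft-min, so small regularization stays numerically sound.
// [[Rcpp::export]]
List cpp_sinkhorn(NumericVector a, NumericVector b, NumericMatrix cost,
                  double reg, int max_iter, double tol) {
  int m = a.size(), n = b.size();
  std::vector<double> f(m, 0.0), g(n, 0.0), la(m), lb(n);
  for (int i = 0; i < m; ++i) la[i] = std::log(std::max((double)a[i], 1e-300));
  for (int j = 0; j < n; ++j) lb[j] = std::log(std::max((double)b[j], 1e-300));
  auto softmin_row = [&](int i) {
    double mx = -1e300;
    for (int j = 0; j < n; ++j)
      mx = std::max(mx, (g[j] - cost(i, j)) / reg + lb[j]);
    double s = 0.0;
    for (int j = 0; j < n; ++j)
      s += std::exp((g[j] - cost(i, j)) / reg + lb[j] - mx);
    return -reg * (mx + std::log(s));
  };
  auto softmin_col = [&](int j) {
    double mx = -1e300;
    for (int i = 0; i < m; ++i)
      mx = std::max(mx, (f[i] - cost(i, j)) / reg + la[i]);
    double s = 0.0;
    for (int i = 0; i < m; ++i)
      s += std::exp((f[i] - cost(i, j)) / reg + la[i] - mx);
    return -reg * (mx + std::log(s));
  };
  for (int it = 0; it < max_iter; ++it) {
    double err = 0.0;
    for (int i = 0; i < m; ++i) f[i] = softmin_row(i);
    for (int j = 0; j < n; ++j) {
      double ng = softmin_col(j);
      err += std::fabs(ng - g[j]);
      g[j] = ng;
    }
    if (err < tol) break;
  }
  // transport cost under the entropic plan
  double c = 0.0;
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < n; ++j) {
      double lp = (f[i] + g[j] - cost(i, j)) / reg + la[i] + lb[j];
      c += std::exp(lp) * cost(i, j);
    }
  return List::create(_["cost"] = c);
}

// ---------------------------------------------------------------------------
// Bisquare-kernel distance-weighted transfer: for each target point, the
// weighted average of donor values within d_max. values: donors x p.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_kernel_smooth(NumericMatrix target, NumericMatrix donor,
                                NumericMatrix values, double d_max,
                                bool exclude_zero_self) {
  int nt = target.nrow(), nd = donor.nrow(), p = values.ncol();
  NumericMatrix out(nt, p);
  double d2max = d_max * d_max;
  std::vector<double> w(nd);
  for (int t = 0; t < nt; ++t) {
    double wsum = 0.0;
    for (int d = 0; d < nd; ++d) {
      double dx = donor(d,0) - target(t,0), dy = donor(d,1) - target(t,1);
      double d2 = dx*dx + dy*dy;
      if (d2 >= d2max) { w[d] = 0.0; continue; }
      if (exclude_zero_self && d2 == 0.0) { w[d] = 0.0; continue; }
      double q = 1.0 - d2 / d2max;
      w[d] = q * q;
      wsum += w[d];
    }
    if (wsum == 0.0) {
      for (int c = 0; c < p; ++c) out(t, c) = NA_REAL;
      continue;
    }
    for (int c = 0; c < p; ++c) {
      double s = 0.0;
      for (int d = 0; d < nd; ++d) if (w[d] > 0.0) s += w[d] * values(d, c);
      out(t, c) = s / wsum;
    }
  }
  return out;
}
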