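// Exact solver for the balanced transportation problem: a bipartite
// network simplex with partial pricing, an artificial-root (big-M) starting
// basis and subtree-size-aware potential updates. This is the computational
// core of the earth mover's distance between sink/source mass distributions
// on the depth-time grid.
//
// Conventions: nodes 0..m-1 are sources, m..m+n-1 demands, node m+n is the
// artificial root. Real arcs are oriented source -> demand with reduced
// cost rc(i,j) = c(i,j) - pi[i] + pi[m+j]; artificial arcs (source -> root,
// root -> demand) carry cost M larger than any path cost, so they drain to
// zero flow. Each non-root node stores its parent arc's flow and
// orientation; a pivot shifts the potentials of the smaller side of the
// basis cut, re-rooting the tree when the root falls on the larger side.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdlib>
#include <limits>

using namespace Rcpp;

namespace {

struct TransportSolver {
  int m, n, N;                 // sources, demands, N = m + n + 1 (with root)
  int art;                     // artificial root node id = m + n
  double M;                    // big-M cost of artificial arcs
  const double *C;             // cost, row-major C[i*n + j]
  std::vector<double> a, b;    // supplies, demands (balanced)
  int root;
  std::vector<int> parent;
  std::vector<double> pflow;   // flow on the arc to the parent
  std::vector<signed char> orient;  // +1: arc child->parent, -1: parent->child
  std::vector<double> pi;      // node potentials
  std::vector<int> size;       // subtree sizes under current rooting
  std::vector<std::vector<int>> adj;  // tree adjacency
  std::vector<long long> stampA, stampB;  // LCA walk stamps
  long long iters = 0;

  TransportSolver(int m_, int n_, const double *C_, double cmax,
                  const std::vector<double> &a_, const std::vector<double> &b_)
    : m(m_), n(n_), N(m_ + n_ + 1), art(m_ + n_), M(4 * cmax + 1), C(C_),
      a(a_), b(b_), root(m_ + n_), parent(N, -1), pflow(N, 0.0),
      orient(N, 0), pi(N, 0.0), size(N, 1), adj(N),
      stampA(N, -1), stampB(N, -1) {}

  inline int dem(int j) const { return m + j; }

  void add_edge(int u, int v) { adj[u].push_back(v); adj[v].push_back(u); }
  void drop_edge(int u, int v) {
    for (size_t k = 0; k < adj[u].size(); ++k)
      if (adj[u][k] == v) { adj[u][k] = adj[u].back(); adj[u].pop_back(); break; }
    for (size_t k = 0; k < adj[v].size(); ++k)
      if (adj[v][k] == u) { adj[v][k] = adj[v].back(); adj[v].pop_back(); break; }
  }

  // star basis: every source feeds the artificial root, the root feeds
  // every demand; all real arcs start with reduced cost c - 2M < 0
  void star_init() {
    adj[art].reserve(m + n);
    for (int i = 0; i < m; ++i) {
      parent[i] = art; pflow[i] = a[i]; orient[i] = +1;  // i -> root
      pi[i] = M;
      add_edge(i, art);
    }
    for (int j = 0; j < n; ++j) {
      int x = dem(j);
      parent[x] = art; pflow[x] = b[j]; orient[x] = -1;  // root -> j
      pi[x] = -M;
      add_edge(x, art);
    }
    pi[art] = 0.0;
    size[art] = N;
  }

  // row-minimum greedy start: each row repeatedly feeds its cheapest
  // unsaturated column; the allocated cells form a forest (an earlier cell
  // in a row always saturated its column), merged along cheapest arcs into
  // a tree that hangs under the artificial root via one zero-flow arc
  std::vector<int> uf;
  int uf_find(int x) {
    while (uf[x] != x) { uf[x] = uf[uf[x]]; x = uf[x]; }
    return x;
  }

  void rowmin_init() {
    std::vector<double> ra = a, rb = b;
    std::vector<char> coldone(n, 0);
    std::vector<std::pair<std::pair<int,int>, double>> arcs;
    uf.assign(N, 0);
    for (int x = 0; x < N; ++x) uf[x] = x;
    int ncols_left = n;
    for (int i = 0; i < m; ++i) {
      const double *row = C + (size_t)i * n;
      while (ra[i] > 0 && ncols_left > 0) {
        int bj = -1;
        double bc = std::numeric_limits<double>::infinity();
        for (int j = 0; j < n; ++j)
          if (!coldone[j] && row[j] < bc) { bc = row[j]; bj = j; }
        if (bj < 0) break;
        double t = std::min(ra[i], rb[bj]);
        ra[i] -= t; rb[bj] -= t;
        arcs.push_back({{i, dem(bj)}, t});
        uf[uf_find(i)] = uf_find(dem(bj));
        if (rb[bj] <= 0) { coldone[bj] = 1; --ncols_left; }
        if (ra[i] <= 0) break;
      }
    }
    // merge remaining components along cheapest source->demand arcs
    while (true) {
      int rc0 = uf_find(0);
      bool all_connected = true;
      for (int i = 0; i < m; ++i) {
        int ci = uf_find(i);
        if (ci == rc0) continue;
        all_connected = false;
        const double *row = C + (size_t)i * n;
        int bj = -1;
        double bc = std::numeric_limits<double>::infinity();
        for (int j = 0; j < n; ++j)
          if (uf_find(dem(j)) != ci && row[j] < bc) { bc = row[j]; bj = j; }
        if (bj >= 0) {
          arcs.push_back({{i, dem(bj)}, 0.0});
          uf[uf_find(i)] = uf_find(dem(bj));
        }
      }
      if (all_connected) break;
    }
    for (int j = 0; j < n; ++j)   // numerical guard; cannot normally happen
      if (uf_find(dem(j)) != uf_find(0)) {
        arcs.push_back({{0, dem(j)}, 0.0});
        uf[uf_find(dem(j))] = uf_find(0);
      }
    // build adjacency, hang node 0's tree under the artificial root
    for (auto &e : arcs) add_edge(e.first.first, e.first.second);
    add_edge(0, art);
    parent[art] = -1; pi[art] = 0.0; root = art;
    std::vector<int> order; order.reserve(N);
    std::vector<int> stack{art};
    std::vector<char> seen(N, 0); seen[art] = 1;
    while (!stack.empty()) {
      int u = stack.back(); stack.pop_back();
      order.push_back(u);
      for (int v : adj[u]) if (!seen[v]) {
        seen[v] = 1; parent[v] = u;
        if (u == art) { pi[v] = M; orient[v] = +1; }       // v = source 0
        else if (u < m) {                                  // v demand
          pi[v] = pi[u] - C[(size_t)u * n + (v - m)];
          orient[v] = -1;
        } else {                                           // v source
          pi[v] = pi[u] + C[(size_t)v * n + (u - m)];
          orient[v] = +1;
        }
        stack.push_back(v);
      }
    }
    for (auto &e : arcs) {
      int u = e.first.first, v = e.first.second;
      if (parent[u] == v) pflow[u] = e.second; else pflow[v] = e.second;
    }
    for (int k = (int)order.size() - 1; k >= 0; --k) {
      int u = order[k];
      if (parent[u] != -1) size[parent[u]] += size[u];
    }
  }

  // ---- pricing ------------------------------------------------------------

  // partial pricing: a rotating major scan harvests candidate arcs with
  // negative reduced cost; minor iterations re-check the list (potentials
  // drift between pivots) and pivot on the most negative remaining one
  size_t next_arc = 0;
  std::vector<int> cand;

  std::pair<int,int> price(double eps) {
    while (!cand.empty()) {
      int bi = -1, bj = -1, bpos = -1;
      double best = -eps;
      size_t w = 0;
      for (size_t p = 0; p < cand.size(); ++p) {
        int k = cand[p];
        int i = k / n, j = k - i * n;
        double rc = C[(size_t)k] - pi[i] + pi[dem(j)];
        if (rc < -eps) {
          cand[w] = k;
          if (rc < best) { best = rc; bi = i; bj = j; bpos = (int)w; }
          ++w;
        }
      }
      cand.resize(w);
      if (bi >= 0) {
        cand[bpos] = cand.back();
        cand.pop_back();
        return {bi, bj};
      }
    }
    size_t narc = (size_t)m * n;
    const size_t want = 64;
    size_t scanned = 0;
    size_t k = next_arc;
    int i = (int)(k / n), j = (int)(k - (size_t)i * n);
    double ui = pi[i];
    while (scanned < narc) {
      const double *row = C + (size_t)i * n;
      for (; j < n && scanned < narc; ++j, ++scanned) {
        double rc = row[j] - ui + pi[m + j];
        if (rc < -eps) cand.push_back(i * n + j);
      }
      if (j == n) { j = 0; ++i; if (i == m) i = 0; ui = pi[i]; }
      if (cand.size() >= want) break;
    }
    next_arc = (size_t)i * n + j;
    if (cand.empty()) return {-1, -1};
    return price(eps);
  }

  // ---- pivot --------------------------------------------------------------

  long long stamp_id = 0;

  // re-root the standalone subtree currently rooted at `from` so that `at`
  // becomes its root, updating flows, orientations and sizes along the
  // reversed path; `total` is the subtree's size
  void reroot(int from, int at, int total) {
    if (at == from) { size[at] = total; return; }
    std::vector<int> path;
    for (int x = at; x != from; x = parent[x]) path.push_back(x);
    path.push_back(from);
    for (size_t idx = path.size() - 1; idx >= 1; --idx)
      size[path[idx]] -= size[path[idx - 1]];
    size[at] = total;
    int cur = at, prev = -1;
    double carry_f = 0.0;
    signed char carry_o = 0;
    while (true) {
      int nxt = parent[cur];
      double f = pflow[cur];
      signed char o = orient[cur];
      parent[cur] = prev;
      pflow[cur] = carry_f;
      orient[cur] = carry_o;
      if (cur == from) break;
      prev = cur; cur = nxt;
      carry_f = f;
      carry_o = (signed char)(-o);   // same arc, reversed child/parent roles
    }
  }

  // add delta to the potentials of the subtree rooted at x
  std::vector<int> dfs_stack;
  void shift_pi(int x, double delta) {
    dfs_stack.clear();
    dfs_stack.push_back(x);
    pi[x] += delta;
    while (!dfs_stack.empty()) {
      int u = dfs_stack.back(); dfs_stack.pop_back();
      for (int v : adj[u]) if (parent[v] == u) {
        pi[v] += delta;
        dfs_stack.push_back(v);
      }
    }
  }

  void pivot(int ei, int ej) {
    int tail = ei, head = dem(ej);
    double rc = C[(size_t)ei * n + ej] - pi[tail] + pi[head];
    // LCA by alternating stamped walks
    ++stamp_id;
    int ua = tail, ub = head, lca = -1;
    stampA[ua] = stamp_id; stampB[ub] = stamp_id;
    while (lca < 0) {
      if (ua != -1) {
        ua = parent[ua];
        if (ua != -1) {
          if (stampB[ua] == stamp_id) { lca = ua; break; }
          stampA[ua] = stamp_id;
        }
      }
      if (ub != -1) {
        ub = parent[ub];
        if (ub != -1) {
          if (stampA[ub] == stamp_id) { lca = ub; break; }
          stampB[ub] = stamp_id;
        }
      }
      if (ua == -1 && ub == -1) stop("transport: cycle walk failed");
    }
    // paths of child nodes strictly below the lca
    std::vector<int> pu, pv;
    for (int x = tail; x != lca; x = parent[x]) pu.push_back(x);
    for (int x = head; x != lca; x = parent[x]) pv.push_back(x);
    // the entering arc pushes theta from tail to head; going around the
    // cycle, head-side arcs are traversed child->parent (flow change
    // +theta when the arc is oriented child->parent), tail-side arcs
    // parent->child (signs reversed)
    double theta = std::numeric_limits<double>::infinity();
    int leave = -1;
    bool leave_on_tail_side = false;
    for (int x : pv) if (orient[x] < 0) {
      if (pflow[x] < theta || (pflow[x] == theta && x < leave)) {
        theta = pflow[x]; leave = x; leave_on_tail_side = false;
      }
    }
    for (int x : pu) if (orient[x] > 0) {
      if (pflow[x] < theta || (leave >= 0 && pflow[x] == theta && x < leave)) {
        theta = pflow[x]; leave = x; leave_on_tail_side = true;
      }
    }
    if (leave < 0) stop("transport: unbounded pivot (should not happen)");
    if (theta < 0) theta = 0;
    for (int x : pv) pflow[x] += (orient[x] > 0 ? theta : -theta);
    for (int x : pu) pflow[x] += (orient[x] > 0 ? -theta : theta);

    int pl = parent[leave];
    // the endpoint of the entering arc inside subtree(leave): tail iff the
    // leaving arc sits on the tail-side path
    int q = leave_on_tail_side ? tail : head;
    int r = leave_on_tail_side ? head : tail;
    double delta = (q == tail) ? rc : -rc;  // potential shift of the cut side

    drop_edge(leave, pl);
    add_edge(tail, head);
    int szcut = size[leave];

    if (2 * szcut <= N) {
      // update the cut side: re-root it at q, attach under r
      for (int x = pl; x != -1; x = parent[x]) size[x] -= szcut;
      reroot(leave, q, szcut);
      parent[q] = r;
      pflow[q] = theta;
      orient[q] = (signed char)(q == tail ? +1 : -1);
      for (int x = r; x != -1; x = parent[x]) size[x] += szcut;
      shift_pi(q, delta);
    } else {
      // update the root side: re-root it at r, attach under q; the cut
      // subtree's local root becomes the global root
      int szroot = N - szcut;
      for (int x = pl; x != -1; x = parent[x]) size[x] -= szcut;
      parent[leave] = -1;
      pflow[leave] = 0.0;
      orient[leave] = 0;
      reroot(root, r, szroot);
      parent[r] = q;
      pflow[r] = theta;
      orient[r] = (signed char)(r == tail ? +1 : -1);
      for (int x = q; x != -1; x = parent[x]) size[x] += szroot;
      root = leave;
      shift_pi(r, -delta);
    }
  }

  // debug audit: rebuild potentials from the basis tree and rescan
  void audit(double eps) {
    std::vector<double> fresh(N, 0.0);
    std::vector<int> stack{root};
    std::vector<char> seen(N, 0); seen[root] = 1;
    fresh[root] = pi[root];
    while (!stack.empty()) {
      int u = stack.back(); stack.pop_back();
      for (int v : adj[u]) if (!seen[v] && parent[v] == u) {
        seen[v] = 1;
        double c;
        int s = -1, d = -1;
        if (u == art || v == art) c = M;
        if (u < m) s = u; else if (u != art) d = u;
        if (v < m) s = v; else if (v != art) d = v;
        if (s >= 0 && d >= 0) c = C[(size_t)s * n + (d - m)];
        // orientation: source -> demand/art, art -> demand
        bool u_is_tail = (u < m) || (u == art && v >= m && v != art);
        fresh[v] = u_is_tail ? fresh[u] - c : fresh[u] + c;
        stack.push_back(v);
      }
    }
    double maxdiff = 0;
    for (int x = 0; x < N; ++x)
      maxdiff = std::max(maxdiff, std::abs(fresh[x] - pi[x]));
    long long nneg = 0;
    double worst = 0;
    for (int i = 0; i < m; ++i)
      for (int j = 0; j < n; ++j) {
        double rc = C[(size_t)i * n + j] - fresh[i] + fresh[m + j];
        if (rc < -eps) { ++nneg; worst = std::min(worst, rc); }
      }
    Rcpp::Rcout << "audit: pi drift " << maxdiff << ", fresh-negative arcs "
                << nneg << " worst " << worst << "\n";
  }

  // ---- driver -------------------------------------------------------------

  double solve(double eps, long long max_iter, bool star = false) {
    if (star) star_init(); else rowmin_init();
    while (true) {
      auto e = price(eps);
      if (e.first < 0) break;
      pivot(e.first, e.second);
      if (++iters > max_iter)
        stop("transport: iteration limit exceeded (%lld pivots)", max_iter);
      if ((iters & 1023) == 0) Rcpp::checkUserInterrupt();
    }
    if (std::getenv("LAMCSD_EMD_AUDIT")) audit(eps);
    double cost = 0.0;
    double art_flow = 0.0, total_flow = 0.0;
    for (double x : a) total_flow += x;
    std::vector<double> bal(N, 0.0);
    for (int x = 0; x < N; ++x) {
      if (parent[x] == -1) continue;
      if (pflow[x] < -1e-9 * total_flow)
        stop("transport: negative basic flow (internal error)");
      int i = x < m ? x : parent[x];
      int j_node = x < m ? parent[x] : x;
      bal[i] += pflow[x];
      bal[j_node] += pflow[x];
      if (x == art || parent[x] == art) { art_flow += pflow[x]; continue; }
      cost += pflow[x] * C[(size_t)i * n + (j_node - m)];
    }
    if (art_flow > 1e-9 * total_flow)
      stop("transport: artificial flow did not drain (imbalanced problem?)");
    for (int i = 0; i < m; ++i)
      if (std::abs(bal[i] - a[i]) > 1e-7 * total_flow)
        stop("transport: supply conservation violated (internal error)");
    for (int j = 0; j < n; ++j)
      if (std::abs(bal[m + j] - b[j]) > 1e-7 * total_flow)
        stop("transport: demand conservation violated (internal error)");
    return cost;
  }
};

} // namespace

// [[Rcpp::export(name = ".emd_cost_matrix")]]
double emd_cost_matrix(NumericVector a, NumericVector b, NumericMatrix cost) {
  int m = a.size(), n = b.size();
  if (cost.nrow() != m || cost.ncol() != n)
    stop("cost matrix dimensions must match mass vectors");
  double sa = 0, sb = 0;
  for (double x : a) { if (x < 0) stop("negative mass"); sa += x; }
  for (double x : b) { if (x < 0) stop("negative mass"); sb += x; }
  if (sa <= 0 || sb <= 0) stop("total mass must be positive");
  if (std::abs(sa - sb) > 1e-6 * std::max(sa, sb))
    stop("mass mismatch beyond tolerance: %g vs %g", sa, sb);
  std::vector<double> av(a.begin(), a.end()), bv(b.begin(), b.end());
  double scale = sa / sb;
  for (auto &x : bv) x *= scale;  // exact balance
  std::vector<double> C((size_t)m * n);
  double cmax = 0;
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < n; ++j) {
      C[(size_t)i * n + j] = cost(i, j);
      cmax = std::max(cmax, std::abs(cost(i, j)));
    }
  TransportSolver s(m, n, C.data(), cmax, av, bv);
  double eps = std::max(1e-12, 1e-11 * cmax);
  double total = s.solve(eps, 3000LL * (m + n) + 10000LL);
  if (std::getenv("LAMCSD_EMD_VERBOSE"))
    Rcpp::Rcout << "emd: " << m << "x" << n << ", pivots " << s.iters << "\n";
  return total;
}

// [[Rcpp::export(name = ".emd_cost_coords")]]
double emd_cost_coords(NumericVector a, NumericVector b,
                       NumericMatrix xa, NumericMatrix xb) {
  int m = a.size(), n = b.size();
  if (xa.nrow() != m || xb.nrow() != n || xa.ncol() != xb.ncol())
    stop("coordinate dimensions must match mass vectors");
  int d = xa.ncol();
  NumericMatrix cost(m, n);
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < n; ++j) {
      double s = 0;
      for (int k = 0; k < d; ++k) {
        double dd = xa(i, k) - xb(j, k);
        s += dd * dd;
      }
      cost(i, j) = std::sqrt(s);
    }
  return emd_cost_matrix(a, b, cost);
}
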