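// Substructure search kernels: maximum common (connected) subgraph via
// branch-and-bound maximum clique on the modular product graph, and
// backtracking subgraph monomorphism enumeration (substructure matching,
// automorphisms). Bond compatibility is passed in as precomputed integer
// codes (0 = no bond); two vertex pairs are compatible when their bond codes
// are equal.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct ProductGraph {
  int n;                          // number of product vertices
  std::vector<int> ai, bj;        // vertex -> (atom in A, atom in B)
  std::vector<std::vector<uint8_t>> adj;  // 0 none, 1 d-edge, 2 c-edge
};

// Build the modular product of two molecular graphs.
ProductGraph build_product(const IntegerMatrix& codeA,
                           const IntegerMatrix& codeB,
                           const LogicalMatrix& atomCompat) {
  const int nA = codeA.nrow(), nB = codeB.nrow();
  ProductGraph pg;
  for (int i = 0; i < nA; ++i)
    for (int j = 0; j < nB; ++j)
      if (atomCompat(i, j)) { pg.ai.push_back(i); pg.bj.push_back(j); }
  pg.n = (int)pg.ai.size();
  pg.adj.assign(pg.n, std::vector<uint8_t>(pg.n, 0));
  for (int u = 0; u < pg.n; ++u) {
    for (int v = u + 1; v < pg.n; ++v) {
      int i1 = pg.ai[u], j1 = pg.bj[u], i2 = pg.ai[v], j2 = pg.bj[v];
      if (i1 == i2 || j1 == j2) continue;
      int ca = codeA(i1, i2), cb = codeB(j1, j2);
      if (ca == cb) {
        uint8_t w = ca > 0 ? 2 : 1;
        pg.adj[u][v] = w;
        pg.adj[v][u] = w;
      }
    }
  }
  return pg;
}

struct CliqueSearch {
  const ProductGraph& pg;
  bool connected;
  long long budget;         // remaining expansion steps
  bool truncated = false;
  std::vector<int> best;    // best clique (product-vertex ids)
  std::vector<int> cur;
  int nA, nB;

  CliqueSearch(const ProductGraph& g, bool conn, long long bud, int nA_, int nB_)
      : pg(g), connected(conn), budget(bud), nA(nA_), nB(nB_) {}

  // bound: clique can grow by at most the number of distinct A-atoms (or
  // B-atoms) among candidates
  int bound(const std::vector<int>& candc, const std::vector<int>& candd) const {
    std::vector<char> sa(nA, 0), sb(nB, 0);
    int da = 0, db = 0;
    for (int v : candc) {
      if (!sa[pg.ai[v]]) { sa[pg.ai[v]] = 1; ++da; }
      if (!sb[pg.bj[v]]) { sb[pg.bj[v]] = 1; ++db; }
    }
    for (int v : candd) {
      if (!sa[pg.ai[v]]) { sa[pg.ai[v]] = 1; ++da; }
      if (!sb[pg.bj[v]]) { sb[pg.bj[v]] = 1; ++db; }
    }
    return std::min(da, db);
  }

  // candc: candidates c-connected to the current clique (extendable now in
  // connected mode); candd: compatible but not yet c-connected
  void expand(std::vector<int>& candc, std::vector<int>& candd) {
    if (budget-- <= 0) { truncated = true; return; }
    if ((int)cur.size() > (int)best.size()) best = cur;
    if (cur.size() + bound(candc, candd) <= best.size()) return;
    std::vector<int>& pool = candc;
    for (size_t idx = 0; idx < pool.size(); ++idx) {
      if (truncated) return;
      if (cur.size() + bound(candc, candd) <= best.size()) return;
      int v = pool[idx];
      cur.push_back(v);
      std::vector<int> nc, nd;
      for (size_t k = idx + 1; k < candc.size(); ++k) {
        int w = candc[k];
        if (pg.adj[v][w]) nc.push_back(w);
      }
      for (int w : candd) {
        if (!pg.adj[v][w]) continue;
        if (!connected || pg.adj[v][w] == 2) nc.push_back(w);
        else nd.push_back(w);
      }
      // promote d-candidates that are c-adjacent to the new vertex is done
      // above; remaining nd stay dormant until some clique member c-links them
      expand(nc, nd);
      cur.pop_back();
    }
  }
};

}  // namespace

// Maximum common (induced) subgraph between two molecules.
// codeA/codeB: nA x nA / nB x nB integer bond-code matrices (0 = no bond).
// atomCompat: nA x nB logical. connected: require the common subgraph to be
// connected. budget: max branch-and-bound expansions before giving up.
// [[Rcpp::export(name = ".cpp_mcs")]]
List cpp_mcs(IntegerMatrix codeA, IntegerMatrix codeB,
             LogicalMatrix atomCompat, bool connected,
             double budget = 5e6) {
  const int nA = codeA.nrow(), nB = codeB.nrow();
  ProductGraph pg = build_product(codeA, codeB, atomCompat);
  CliqueSearch cs(pg, connected, (long long)budget, nA, nB);
  // seed loop: vertex v starts a clique; only vertices after v are candidates
  // (any clique has a least vertex, so this enumerates all maximal cliques)
  for (int v = 0; v < pg.n && !cs.truncated; ++v) {
    cs.cur.assign(1, v);
    std::vector<int> candc, candd;
    for (int w = v + 1; w < pg.n; ++w) {
      if (!pg.adj[v][w]) continue;
      if (!connected || pg.adj[v][w] == 2) candc.push_back(w);
      else candd.push_back(w);
    }
    if (1 + cs.bound(candc, candd) > (int)cs.best.size())
      cs.expand(candc, candd);
  }
  IntegerMatrix mapping(cs.best.size(), 2);
  std::vector<int> bs = cs.best;
  std::sort(bs.begin(), bs.end(), [&](int a, int b) {
    return pg.ai[a] < pg.ai[b];
  });
  for (size_t k = 0; k < bs.size(); ++k) {
    mapping(k, 0) = pg.ai[bs[k]] + 1;
    mapping(k, 1) = pg.bj[bs[k]] + 1;
  }
  return List::create(_["size"] = (int)cs.best.size(),
                      _["mapping"] = mapping,
                      _["truncated"] = cs.truncated);
}

namespace {

struct MonoSearch {
  const IntegerMatrix& codeQ;   // query bond codes
  const IntegerMatrix& codeT;   // target bond codes
  const LogicalMatrix& compat;  // nQ x nT atom compatibility
  bool induced;                 // also forbid target bonds absent in query
  int maxCount;
  long long budget;
  bool truncated = false;
  int nQ, nT;
  std::vector<int> order;       // query vertices in connected BFS order
  std::vector<int> assign_;     // query -> target (-1 unset)
  std::vector<char> used;       // target used flags
  std::vector<std::vector<int>> results;

  MonoSearch(const IntegerMatrix& q, const IntegerMatrix& t,
             const LogicalMatrix& c, bool ind, int maxc, long long bud)
      : codeQ(q), codeT(t), compat(c), induced(ind), maxCount(maxc),
        budget(bud), nQ(q.nrow()), nT(t.nrow()),
        assign_(q.nrow(), -1), used(t.nrow(), 0) {
    // BFS order over the query graph, components chained
    std::vector<char> seen(nQ, 0);
    for (int s = 0; s < nQ; ++s) {
      if (seen[s]) continue;
      std::vector<int> queue{s};
      seen[s] = 1;
      while (!queue.empty()) {
        int v = queue.front();
        queue.erase(queue.begin());
        order.push_back(v);
        for (int w = 0; w < nQ; ++w)
          if (!seen[w] && codeQ(v, w) > 0) { seen[w] = 1; queue.push_back(w); }
      }
    }
  }

  void search(size_t depth) {
    if (truncated || (int)results.size() >= maxCount) return;
    if (budget-- <= 0) { truncated = true; return; }
    if (depth == order.size()) {
      results.push_back(assign_);
      return;
    }
    int q = order[depth];
    for (int t = 0; t < nT; ++t) {
      if (used[t] || !compat(q, t)) continue;
      bool ok = true;
      for (size_t d = 0; d < depth && ok; ++d) {
        int q2 = order[d], t2 = assign_[q2];
        int cq = codeQ(q, q2), ct = codeT(t, t2);
        if (cq > 0) ok = (cq == ct);
        else if (induced) ok = (ct == 0);
      }
      if (!ok) continue;
      assign_[q] = t;
      used[t] = 1;
      search(depth + 1);
      assign_[q] = -1;
      used[t] = 0;
    }
  }
};

}  // namespace

// Enumerate subgraph monomorphisms of the query into the target (up to
// max_count). induced=true restricts to induced embeddings (used for
// automorphism enumeration).
// [[Rcpp::export(name = ".cpp_monomorphisms")]]
List cpp_monomorphisms(IntegerMatrix codeQ, IntegerMatrix codeT,
                       LogicalMatrix atomCompat, bool induced,
                       int max_count, double budget = 5e6) {
  MonoSearch ms(codeQ, codeT, atomCompat, induced, max_count,
                (long long)budget);
  ms.search(0);
  List maps(ms.results.size());
  for (size_t k = 0; k < ms.results.size(); ++k) {
    IntegerVector m(ms.nQ);
    for (int q = 0; q < ms.nQ; ++q) m[q] = ms.results[k][q] + 1;
    maps[k] = m;
  }
  return List::create(_["mappings"] = maps, _["truncated"] = ms.truncated);
}
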