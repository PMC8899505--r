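// Maximum common induced subgraph by partition-based branch and bound
// (McSplit-style). Vertices of the two graphs are kept in label classes that
// are split by bond codes to each newly mapped pair; the bound is the mapped
// count plus the sum over classes of min(|A side|, |B side|). Supports
// edge-labelled graphs (integer bond codes, 0 = no bond) and an optional
// connectivity requirement on the common subgraph.

#include <Rcpp.h>
#include <vector>
#include <map>
#include <algorithm>
using namespace Rcpp;

namespace {

struct LabelClass {
  std::vector<int> va, vb;
  bool conn;  // adjacent to the current mapping (for connected mode)
};

struct McSplit {
  const IntegerMatrix& codeA;
  const IntegerMatrix& codeB;
  bool connected;
  long long budget;
  bool truncated = false;
  std::vector<std::pair<int, int>> cur, best;

  McSplit(const IntegerMatrix& a, const IntegerMatrix& b, bool conn,
          long long bud)
      : codeA(a), codeB(b), connected(conn), budget(bud) {}

  static int bound_of(const std::vector<LabelClass>& classes) {
    int s = 0;
    for (const auto& c : classes)
      s += std::min((int)c.va.size(), (int)c.vb.size());
    return s;
  }

  void search(std::vector<LabelClass>& classes) {
    if (truncated) return;
    if (budget-- <= 0) { truncated = true; return; }
    if (cur.size() > best.size()) best = cur;
    if ((int)cur.size() + bound_of(classes) <= (int)best.size()) return;
    // pick the class (eligible in connected mode) minimizing max side size;
    // ties by first occurrence for determinism
    int ci = -1;
    size_t cbest = SIZE_MAX;
    for (size_t k = 0; k < classes.size(); ++k) {
      const auto& c = classes[k];
      if (c.va.empty() || c.vb.empty()) continue;
      if (connected && !cur.empty() && !c.conn) continue;
      size_t m = std::max(c.va.size(), c.vb.size());
      if (m < cbest) { cbest = m; ci = (int)k; }
    }
    if (ci < 0) return;
    // branch vertex: smallest index in the A side (deterministic)
    int v = *std::min_element(classes[ci].va.begin(), classes[ci].va.end());
    std::vector<int> bs = classes[ci].vb;
    std::sort(bs.begin(), bs.end());
    for (int w : bs) {
      cur.emplace_back(v, w);
      std::vector<LabelClass> next;
      next.reserve(classes.size() * 2);
      for (const auto& c : classes) {
        // split by bond code to (v, w); only matching codes survive
        std::map<int, LabelClass> parts;
        for (int x : c.va)
          if (x != v) parts[codeA(x, v)].va.push_back(x);
        for (int y : c.vb)
          if (y != w) parts[codeB(y, w)].vb.push_back(y);
        for (auto& kv : parts) {
          if (kv.second.va.empty() || kv.second.vb.empty()) continue;
          kv.second.conn = c.conn || kv.first > 0;
          next.push_back(std::move(kv.second));
        }
      }
      search(next);
      cur.pop_back();
      if (truncated) return;
    }
    // branch: v stays unmatched
    std::vector<LabelClass> rest = classes;
    auto& va = rest[ci].va;
    va.erase(std::remove(va.begin(), va.end(), v), va.end());
    search(rest);
  }
};

}  // namespace

// keysA/keysB: integer atom-equivalence labels (shared level coding).
// [[Rcpp::export(name = ".cpp_mcsplit")]]
List cpp_mcsplit(IntegerMatrix codeA, IntegerMatrix codeB,
                 IntegerVector keysA, IntegerVector keysB, bool connected,
                 double budget = 1e7) {
  McSplit ms(codeA, codeB, connected, (long long)budget);
  std::map<int, LabelClass> init;
  for (int i = 0; i < keysA.size(); ++i) init[keysA[i]].va.push_back(i);
  for (int j = 0; j < keysB.size(); ++j) init[keysB[j]].vb.push_back(j);
  std::vector<LabelClass> classes;
  for (auto& kv : init) {
    if (kv.second.va.empty() || kv.second.vb.empty()) continue;
    kv.second.conn = false;
    classes.push_back(std::move(kv.second));
  }
  ms.search(classes);
  std::sort(ms.best.begin(), ms.best.end());
  IntegerMatrix mapping(ms.best.size(), 2);
  for (size_t k = 0; k < ms.best.size(); ++k) {
    mapping(k, 0) = ms.best[k].first + 1;
    mapping(k, 1) = ms.best[k].second + 1;
  }
  return List::create(_["size"] = (int)ms.best.size(),
                      _["mapping"] = mapping,
                      _["truncated"] = ms.truncated);
}
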