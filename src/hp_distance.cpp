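#include <Rcpp.h>
#include <vector>
#include <map>
#include <set>
#include <algorithm>
#include <functional>
using namespace Rcpp;

// Hannenhalli-Pevzner signed reversal distance machinery: breakpoint graph
// cycle count, unoriented-component hurdles (minimal + greatest via the
// circular-consecutiveness test) and the fortress condition.

static std::set<int> hurdle_set_of(const std::vector<int>& seqlab) {
  std::set<int> out;
  const int L = (int)seqlab.size();
  if (L == 0) return out;
  std::map<int, int> breaks;
  for (int i = 0; i < L; ++i) {
    int nxt = seqlab[(i + 1) % L];
    if (seqlab[i] != nxt) breaks[seqlab[i]] += 1;
    else breaks.emplace(seqlab[i], 0);
  }
  for (auto& kv : breaks)
    if (kv.second <= 1) out.insert(kv.first);
  return out;
}

// [[Rcpp::export(name = ".hp_reversal")]]
List hp_reversal(IntegerVector perm) {
  const int n = perm.size();
  if (n == 0) return List::create(_["distance"] = 0, _["c"] = 1,
                                  _["h"] = 0, _["f"] = 0);
  const int m = 2 * n + 2;
  std::vector<int> u(m), pos(m);
  u[0] = 0;
  for (int t = 1; t <= n; ++t) {
    int x = perm[t - 1];
    if (x > 0) { u[2 * t - 1] = 2 * x - 1; u[2 * t] = 2 * x; }
    else       { u[2 * t - 1] = -2 * x;    u[2 * t] = -2 * x - 1; }
  }
  u[m - 1] = 2 * n + 1;
  for (int p = 0; p < m; ++p) pos[u[p]] = p;

  // cycle ids per position; walk alternating black (position xor 1) and
  // gray (value xor 1) partners
  std::vector<int> cyc(m, 0);
  int ncyc = 0;
  for (int start = 0; start < m; ++start) {
    if (cyc[start]) continue;
    ++ncyc;
    int p = start;
    for (;;) {
      cyc[p] = ncyc;
      int p2 = p ^ 1;
      cyc[p2] = ncyc;
      p = pos[u[p2] ^ 1];
      if (p == start) break;
    }
  }

  // gray edges t = 0..n between values 2t and 2t+1
  const int g = n + 1;
  std::vector<int> gp(g), gq(g), gcyc(g);
  std::vector<bool> oriented(g);
  std::vector<int> cyc_size(ncyc + 1, 0);
  for (int p = 0; p < m; ++p) cyc_size[cyc[p]] += 1;
  std::vector<bool> cyc_has_oriented(ncyc + 1, false);
  std::vector<bool> cyc_nontrivial(ncyc + 1, false);
  for (int t = 0; t < g; ++t) {
    int a = pos[2 * t], b = pos[2 * t + 1];
    gp[t] = std::min(a, b);
    gq[t] = std::max(a, b);
    gcyc[t] = cyc[gp[t]];
    oriented[t] = ((gp[t] + gq[t]) % 2) == 0;
    if (cyc_size[gcyc[t]] > 2) {
      cyc_nontrivial[gcyc[t]] = true;
      if (oriented[t]) cyc_has_oriented[gcyc[t]] = true;
    }
  }

  int h = 0, f = 0;
  bool any_unoriented = false;
  for (int c = 1; c <= ncyc; ++c)
    if (cyc_nontrivial[c] && !cyc_has_oriented[c]) any_unoriented = true;

  if (any_unoriented) {
    // interleaving graph over non-trivial cycles (union-find)
    std::vector<int> parent(ncyc + 1);
    for (int i = 0; i <= ncyc; ++i) parent[i] = i;
    std::function<int(int)> find = [&](int x) {
      while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
      return x;
    };
    std::vector<int> e;
    for (int t = 0; t < g; ++t)
      if (cyc_size[gcyc[t]] > 2) e.push_back(t);
    for (size_t i = 0; i + 1 < e.size(); ++i) {
      for (size_t j = i + 1; j < e.size(); ++j) {
        int a = e[i], b = e[j];
        if (gcyc[a] == gcyc[b]) continue;
        bool in1 = gp[b] > gp[a] && gp[b] < gq[a];
        bool in2 = gq[b] > gp[a] && gq[b] < gq[a];
        if (in1 != in2) {
          int ra = find(gcyc[a]), rb = find(gcyc[b]);
          if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
        }
      }
    }
    // component orientation
    std::map<int, bool> comp_oriented;
    for (int t : e) {
      int cc = find(gcyc[t]);
      auto it = comp_oriented.find(cc);
      bool o = oriented[t];
      if (it == comp_oriented.end()) comp_oriented[cc] = o;
      else it->second = it->second || o;
    }
    std::set<int> unor;
    for (auto& kv : comp_oriented)
      if (!kv.second) unor.insert(kv.first);
    if (!unor.empty()) {
      // endpoints of gray edges of unoriented components, in position order
      std::vector<std::pair<int, int>> lab;   // (position, component)
      for (int t : e) {
        int cc = find(gcyc[t]);
        if (unor.count(cc)) {
          lab.emplace_back(gp[t], cc);
          lab.emplace_back(gq[t], cc);
        }
      }
      std::sort(lab.begin(), lab.end());
      std::vector<int> seqlab;
      seqlab.reserve(lab.size());
      for (auto& pr : lab) seqlab.push_back(pr.second);
      std::set<int> hs = hurdle_set_of(seqlab);
      h = (int)hs.size();
      if (h % 2 == 1 && h >= 3) {
        bool all_super = true;
        for (int u0 : hs) {
          std::vector<int> rest;
          for (int x : seqlab) if (x != u0) rest.push_back(x);
          std::set<int> hs2 = hurdle_set_of(rest);
          bool newly = false;
          for (int w : hs2) if (!hs.count(w)) { newly = true; break; }
          if (!newly) { all_super = false; break; }
        }
        if (all_super) f = 1;
      }
    }
  }
  int d = n + 1 - ncyc + h + f;
  return List::create(_["distance"] = d, _["c"] = ncyc,
                      _["h"] = h, _["f"] = f);
}
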