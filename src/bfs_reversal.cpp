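#include <Rcpp.h>
#include <unordered_map>
#include <deque>
#include <cstdint>
using namespace Rcpp;

// Brute-force reference for the signed reversal distance: breadth-first
// search over the whole space of signed permutations of 1..n, used as an
// independent oracle in tests. Feasible for n <= 8.

static inline std::uint64_t encode(const std::vector<int>& p, int n) {
  std::uint64_t key = 0;
  const std::uint64_t base = 2 * n;
  for (int i = 0; i < n; ++i) {
    int v = p[i];
    std::uint64_t digit = (std::uint64_t)((std::abs(v) - 1) * 2 + (v < 0));
    key = key * base + digit;
  }
  return key;
}

// [[Rcpp::export(name = ".bfs_reversal_distance")]]
IntegerVector bfs_reversal_distance(int n, IntegerMatrix queries) {
  if (n < 1 || n > 8) stop("BFS oracle supports 1 <= n <= 8");
  std::unordered_map<std::uint64_t, int> dist;
  std::vector<int> ident(n);
  for (int i = 0; i < n; ++i) ident[i] = i + 1;
  std::deque<std::vector<int>> queue;
  dist[encode(ident, n)] = 0;
  queue.push_back(ident);
  while (!queue.empty()) {
    std::vector<int> cur = queue.front();
    queue.pop_front();
    int d = dist[encode(cur, n)];
    for (int i = 0; i < n; ++i) {
      for (int j = i; j < n; ++j) {
        std::vector<int> nxt = cur;
        for (int a = i, b = j; a <= b; ++a, --b) {
          int tmp = nxt[a];
          nxt[a] = -nxt[b];
          nxt[b] = -tmp;
        }
        std::uint64_t key = encode(nxt, n);
        if (dist.find(key) == dist.end()) {
          dist[key] = d + 1;
          queue.push_back(nxt);
        }
      }
    }
  }
  IntegerVector out(queries.nrow());
  for (int r = 0; r < queries.nrow(); ++r) {
    std::vector<int> q(n);
    for (int i = 0; i < n; ++i) q[i] = queries(r, i);
    auto it = dist.find(encode(q, n));
    if (it == dist.end()) stop("query row %d is not a signed permutation", r + 1);
    out[r] = it->second;
  }
  return out;
}
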