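// Layered construction of the potential graph: starting from the observed
// (deduplicated) cell strings, repeatedly pair up all current source nodes
// (in-degree 0), and for pairs within edit distance d add their latest
// common ancestor with edges to both, until a single source remains.
// Missing entries (-1) act as wildcards: they match any state and
// contribute 0 to edit distances; the LCA adopts the non-missing side.

#include <Rcpp.h>
#include <map>
#include <set>
#include <vector>
using namespace Rcpp;

typedef std::vector<int> Str;

static inline int edit_dist(const Str& a, const Str& b, int stop_above) {
  int d = 0;
  for (size_t c = 0; c < a.size(); ++c) {
    if (a[c] >= 0 && b[c] >= 0 && a[c] != b[c]) {
      if (++d > stop_above) return d;
    }
  }
  return d;
}

static inline Str lca_of(const Str& a, const Str& b) {
  Str out(a.size());
  for (size_t c = 0; c < a.size(); ++c) {
    if (a[c] < 0 && b[c] < 0) out[c] = -1;
    else if (a[c] < 0) out[c] = b[c];
    else if (b[c] < 0) out[c] = a[c];
    else out[c] = (a[c] == b[c]) ? a[c] : 0;
  }
  return out;
}

// [[Rcpp::export(name = ".potential_graph_cpp")]]
List potential_graph_cpp(IntegerMatrix cells, int d, int max_nodes,
                         IntegerVector root_string) {
  const int m = cells.ncol();
  std::vector<Str> nodes;
  std::map<Str, int> index;
  std::vector<int> indeg;
  std::map<std::pair<int,int>, int> edges; // (from,to) -> weight

  auto add_node = [&](const Str& s) -> int {
    auto it = index.find(s);
    if (it != index.end()) return it->second;
    int id = (int)nodes.size();
    nodes.push_back(s);
    index[s] = id;
    indeg.push_back(0);
    return id;
  };
  auto add_edge = [&](int from, int to) {
    if (from == to) return;
    auto key = std::make_pair(from, to);
    if (edges.count(key)) return;
    int w = edit_dist(nodes[from], nodes[to], m + 1);
    edges[key] = w;
    indeg[to]++;
  };

  for (int r = 0; r < cells.nrow(); ++r) {
    Str s(m);
    for (int c = 0; c < m; ++c) s[c] = cells(r, c);
    add_node(s);
  }
  Str root(m);
  for (int c = 0; c < m; ++c) root[c] = root_string[c];

  bool capped = false;
  while (true) {
    std::vector<int> sources;
    for (size_t v = 0; v < nodes.size(); ++v)
      if (indeg[v] == 0) sources.push_back((int)v);
    if (sources.size() <= 1) break;

    size_t nodes_before = nodes.size();
    size_t edges_before = edges.size();
    size_t ns = sources.size();
    for (size_t i = 0; i < ns && !capped; ++i) {
      for (size_t j = i + 1; j < ns; ++j) {
        int u = sources[i], v = sources[j];
        // paper's rule: pair qualifies when strictly below the threshold
        if (d < 1 || edit_dist(nodes[u], nodes[v], d - 1) >= d) continue;
        Str anc = lca_of(nodes[u], nodes[v]);
        int a = add_node(anc);
        if ((int)nodes.size() > max_nodes) { capped = true; break; }
        add_edge(a, u);
        add_edge(a, v);
      }
    }
    if (capped) break;
    if (nodes.size() == nodes_before && edges.size() == edges_before) {
      // stagnation: no pair within distance d; connect remaining sources
      // to the designated root
      int rid = add_node(root);
      if ((int)nodes.size() > max_nodes) { capped = true; break; }
      for (int s : sources) add_edge(rid, s);
      break;
    }
  }

  // if a single source remains but it is not the designated root, attach it
  if (!capped) {
    std::vector<int> sources;
    for (size_t v = 0; v < nodes.size(); ++v)
      if (indeg[v] == 0) sources.push_back((int)v);
    auto it = index.find(root);
    int rid = (it == index.end()) ? -1 : it->second;
    if (!(sources.size() == 1 && sources[0] == rid)) {
      rid = add_node(root);
      if ((int)nodes.size() > max_nodes) capped = true;
      else for (int s : sources) if (s != rid) add_edge(rid, s);
    }
  }

  IntegerMatrix nm((int)nodes.size(), m);
  for (size_t v = 0; v < nodes.size(); ++v)
    for (int c = 0; c < m; ++c) nm((int)v, c) = nodes[v][c];
  IntegerMatrix em((int)edges.size(), 3);
  int k = 0;
  for (auto& e : edges) {
    em(k, 0) = e.first.first + 1;   // 1-based for R
    em(k, 1) = e.first.second + 1;
    em(k, 2) = e.second;
    ++k;
  }
  auto rit = index.find(root);
  int root_id = (rit == index.end()) ? NA_INTEGER : rit->second + 1;
  return List::create(_["nodes"] = nm, _["edges"] = em,
                      _["root"] = root_id, _["capped"] = capped);
}
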