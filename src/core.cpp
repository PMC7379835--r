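#include "graph_core.h"

using namespace Rcpp;

Graph build_graph(const List& gl) {
  Graph g;
  CharacterVector labs = gl["labels"];
  IntegerVector rc = gl["rc"];
  IntegerVector lf = gl["link_from"], lt = gl["link_to"], lo = gl["link_ov"];
  g.m = labs.size();
  g.lab.resize(g.m);
  g.rc.resize(g.m);
  g.out.assign(g.m, {});
  g.in.assign(g.m, {});
  for (int i = 0; i < g.m; ++i) {
    g.lab[i] = as<std::string>(labs[i]);
    g.rc[i] = rc[i] - 1;
  }
  for (int j = 0; j < lf.size(); ++j) {
    int a = lf[j] - 1, b = lt[j] - 1, ov = lo[j];
    g.out[a].push_back({b, ov});
    g.in[b].push_back({a, ov});
  }
  g.posoff.resize(g.m + 1);
  g.posoff[0] = 0;
  for (int i = 0; i < g.m; ++i) g.posoff[i + 1] = g.posoff[i] + g.len(i) + 1;
  g.total_pos = g.posoff[g.m];
  return g;
}

char translate_codon(int b1, int b2, int b3) {
  if (b1 > 3 || b2 > 3 || b3 > 3) return 'X';
  // Standard code spelt out by first base blocks (A,C,G,T order).
  static const char* tab[4] = {
      // b1 = A: AAA..ATT
      "KNKNTTTTRSRSIIMI",
      // b1 = C
      "QHQHPPPPRRRRLLLL",
      // b1 = G
      "EDEDAAAAGGGGVVVV",
      // b1 = T
      "*Y*YSSSS*CWCLFLF"};
  return tab[b1][b2 * 4 + b3];
}

// [[Rcpp::export]]
std::vector<std::string> cpp_revcomp(std::vector<std::string> x) {
  for (auto& s : x) s = revcomp_str(s);
  return x;
}

// [[Rcpp::export]]
std::vector<std::string> cpp_translate(std::vector<std::string> x) {
  std::vector<std::string> out;
  out.reserve(x.size());
  for (const auto& s : x) {
    if (s.size() % 3 != 0)
      stop("nucleotide sequence length %d is not divisible by 3", (int)s.size());
    std::string p;
    p.reserve(s.size() / 3);
    for (size_t i = 0; i + 2 < s.size(); i += 3)
      p.push_back(translate_codon(base_code(s[i]), base_code(s[i + 1]),
                                  base_code(s[i + 2])));
    out.push_back(p);
  }
  return out;
}

// Minimal label-length distance (bp) between two graph positions.
// Dijkstra over link-arrival states (edge, entry overlap); the direct
// same-edge walk is handled separately and is always optimal when o1 <= o2.
// [[Rcpp::export]]
double cpp_min_graph_distance(List gl, int e1, int o1, int e2, int o2,
                              double cap) {
  Graph g = build_graph(gl);
  --e1; --e2;
  double best = R_PosInf;
  if (e1 == e2 && o1 <= o2) best = o2 - o1;
  typedef std::pair<double, int64_t> QE;  // (dist at (e,ov), e*2^32|ov)
  std::priority_queue<QE, std::vector<QE>, std::greater<QE>> pq;
  std::unordered_map<int64_t, double> dist;
  double d0 = g.len(e1) - o1;
  for (auto& lnk : g.out[e1]) {
    int64_t key = (static_cast<int64_t>(lnk.first) << 32) | lnk.second;
    if (!dist.count(key) || d0 < dist[key]) {
      dist[key] = d0;
      pq.push({d0, key});
    }
  }
  while (!pq.empty()) {
    auto [d, key] = pq.top();
    pq.pop();
    if (d > cap || d >= best) break;
    auto it = dist.find(key);
    if (it == dist.end() || it->second < d) continue;
    int e = static_cast<int>(key >> 32), ov = static_cast<int>(key & 0xffffffff);
    if (e == e2 && o2 >= ov) best = std::min(best, d + (o2 - ov));
    double dx = d + (g.len(e) - ov);
    for (auto& lnk : g.out[e]) {
      int64_t k2 = (static_cast<int64_t>(lnk.first) << 32) | lnk.second;
      auto it2 = dist.find(k2);
      if (it2 == dist.end() || dx < it2->second) {
        dist[k2] = dx;
        pq.push({dx, k2});
      }
    }
  }
  if (best > cap) return R_PosInf;
  return best;
}

// Edges whose entry point is reachable within `radius` bp from any seed
// position, following links forward. Seed edges are always included.
// [[Rcpp::export]]
IntegerVector cpp_reach_forward(List gl, IntegerVector seed_e,
                                IntegerVector seed_o, double radius) {
  Graph g = build_graph(gl);
  std::vector<double> arr(g.m, R_PosInf);
  typedef std::pair<double, int64_t> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE>> pq;
  std::unordered_map<int64_t, double> dist;
  std::unordered_set<int> keep;
  for (int i = 0; i < seed_e.size(); ++i) {
    int e = seed_e[i] - 1, o = seed_o[i];
    keep.insert(e);
    double d0 = g.len(e) - o;
    for (auto& lnk : g.out[e]) {
      int64_t key = (static_cast<int64_t>(lnk.first) << 32) | lnk.second;
      if (!dist.count(key) || d0 < dist[key]) {
        dist[key] = d0;
        pq.push({d0, key});
      }
    }
  }
  while (!pq.empty()) {
    auto [d, key] = pq.top();
    pq.pop();
    if (d > radius) break;
    auto it = dist.find(key);
    if (it == dist.end() || it->second < d) continue;
    int e = static_cast<int>(key >> 32), ov = static_cast<int>(key & 0xffffffff);
    if (d < arr[e]) arr[e] = d;
    keep.insert(e);
    double dx = d + (g.len(e) - ov);
    for (auto& lnk : g.out[e]) {
      int64_t k2 = (static_cast<int64_t>(lnk.first) << 32) | lnk.second;
      auto it2 = dist.find(k2);
      if (it2 == dist.end() || dx < it2->second) {
        dist[k2] = dx;
        pq.push({dx, k2});
      }
    }
  }
  IntegerVector res(keep.size());
  int i = 0;
  for (int e : keep) res[i++] = e + 1;
  std::sort(res.begin(), res.end());
  return res;
}

// Walk an exact sequence through the graph using a k-mer index of the edge
// labels; used to recover ground-truth paths for simulated data.
// [[Rcpp::export]]
List cpp_trace_path(List gl, std::string seq, int k) {
  Graph g = build_graph(gl);
  if (static_cast<int>(seq.size()) < k) stop("sequence shorter than k");
  std::unordered_map<std::string, std::pair<int, int>> idx;
  for (int e = 0; e < g.m; ++e) {
    const std::string& L = g.lab[e];
    for (int i = 0; i + k <= static_cast<int>(L.size()); ++i)
      idx.emplace(L.substr(i, k), std::make_pair(e, i));
  }
  auto it = idx.find(seq.substr(0, k));
  if (it == idx.end()) stop("leading k-mer of the sequence is not in the graph");
  int e = it->second.first;
  int start_off = it->second.second;
  int lab_pos = start_off + k;
  std::vector<int> edges{e};
  for (size_t i = k; i < seq.size(); ++i) {
    if (lab_pos == g.len(e)) {
      int nxt = -1, nov = 0;
      for (auto& lnk : g.out[e]) {
        const std::string& L2 = g.lab[lnk.first];
        if (lnk.second < static_cast<int>(L2.size()) &&
            L2[lnk.second] == seq[i]) {
          nxt = lnk.first;
          nov = lnk.second;
          break;
        }
      }
      if (nxt < 0) stop("sequence leaves the graph at position %d", (int)i);
      e = nxt;
      lab_pos = nov;
      edges.push_back(e);
    }
    if (g.lab[e][lab_pos] != seq[i])
      stop("sequence mismatches the graph at position %d", (int)i);
    ++lab_pos;
  }
  IntegerVector ev(edges.size());
  for (size_t j = 0; j < edges.size(); ++j) ev[j] = edges[j] + 1;
  return List::create(_["edges"] = ev, _["start_offset"] = start_off,
                      _["end_offset"] = lab_pos);
}
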