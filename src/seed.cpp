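#include "graph_core.h"

using namespace Rcpp;

// Exact k-mer seeding of a query against edge labels, with merging of
// co-diagonal seeds into exact runs and colinear chaining of nearby runs
// (bounded gap and diagonal drift) into gapped anchors. Returns one row per
// anchor: edge (1-based), qs, qe, es, ee (0-based half-open ranges).

namespace {

struct Run {
  int qs, qe, es, ee;
};

inline bool encode_kmer(const std::string& s, int pos, int k, uint64_t& out) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int b = base_code(s[pos + i]);
    if (b > 3) return false;
    v = (v << 2) | static_cast<uint64_t>(b);
  }
  out = v;
  return true;
}

}  // namespace

// [[Rcpp::export]]
IntegerMatrix cpp_find_anchors(List gl, std::string query, int k_seed,
                               int min_span, int max_gap, int max_occ) {
  if (k_seed < 4 || k_seed > 31) stop("k_seed must be in 4..31");
  Graph g = build_graph(gl);
  int lq = query.size();
  std::unordered_map<uint64_t, std::vector<int>> qk;
  for (int i = 0; i + k_seed <= lq; ++i) {
    uint64_t v;
    if (encode_kmer(query, i, k_seed, v)) qk[v].push_back(i);
  }

  std::vector<std::array<int, 5>> anchors;  // edge, qs, qe, es, ee
  for (int e = 0; e < g.m; ++e) {
    const std::string& L = g.lab[e];
    int ll = L.size();
    if (ll < k_seed) continue;
    // seeds on this edge
    std::vector<std::pair<int, int>> seeds;  // (qpos, epos)
    for (int j = 0; j + k_seed <= ll; ++j) {
      uint64_t v;
      if (!encode_kmer(L, j, k_seed, v)) continue;
      auto it = qk.find(v);
      if (it == qk.end()) continue;
      if (static_cast<int>(it->second.size()) > max_occ) continue;
      for (int i : it->second) seeds.push_back({i, j});
    }
    if (seeds.empty()) continue;
    // merge co-diagonal overlapping seeds into maximal exact runs
    std::sort(seeds.begin(), seeds.end(),
              [](const std::pair<int, int>& a, const std::pair<int, int>& b) {
                int da = a.second - a.first, db = b.second - b.first;
                if (da != db) return da < db;
                return a.first < b.first;
              });
    std::vector<Run> runs;
    for (auto& s : seeds) {
      if (!runs.empty()) {
        Run& r = runs.back();
        if (s.second - s.first == r.es - r.qs && s.first <= r.qe) {
          r.qe = std::max(r.qe, s.first + k_seed);
          r.ee = std::max(r.ee, s.second + k_seed);
          continue;
        }
      }
      runs.push_back({s.first, s.first + k_seed, s.second, s.second + k_seed});
    }
    // colinear chaining of runs into gapped anchors
    std::sort(runs.begin(), runs.end(), [](const Run& a, const Run& b) {
      if (a.qs != b.qs) return a.qs < b.qs;
      return a.es < b.es;
    });
    std::vector<Run> open;
    for (auto& r : runs) {
      int best = -1, best_qe = -1;
      for (size_t a = 0; a < open.size(); ++a) {
        const Run& A = open[a];
        int gq = r.qs - A.qe, ge = r.es - A.ee;
        if (gq < -k_seed || ge < -k_seed) continue;
        if (gq > max_gap || ge > max_gap) continue;
        int drift = std::abs((r.es - r.qs) - (A.ee - A.qe));
        int allow = std::max(15, (std::max(gq, ge) * 7) / 20);
        if (drift > allow) continue;
        if (r.qe <= A.qe || r.ee <= A.ee) continue;
        if (A.qe > best_qe) { best_qe = A.qe; best = static_cast<int>(a); }
      }
      if (best >= 0) {
        open[best].qe = r.qe;
        open[best].ee = r.ee;
      } else {
        open.push_back(r);
      }
    }
    for (auto& A : open)
      if (A.qe - A.qs >= min_span)
        anchors.push_back({e + 1, A.qs, A.qe, A.es, A.ee});
  }
  std::sort(anchors.begin(), anchors.end(),
            [](const std::array<int, 5>& a, const std::array<int, 5>& b) {
              if (a[1] != b[1]) return a[1] < b[1];
              if (a[0] != b[0]) return a[0] < b[0];
              return a[3] < b[3];
            });
  IntegerMatrix res(anchors.size(), 5);
  for (size_t i = 0; i < anchors.size(); ++i)
    for (int j = 0; j < 5; ++j) res(i, j) = anchors[i][j];
  colnames(res) = CharacterVector::create("edge", "qs", "qe", "es", "ee");
  return res;
}
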