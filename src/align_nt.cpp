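#include "graph_core.h"

using namespace Rcpp;

// Shortest-path search over the implicit alignment graph SG(G, sub).
// States are <graph position, query position>; edges encode deletion
// (graph char consumed, cost sigma), insertion (query char consumed, cost
// sigma), diagonal (both consumed, cost 0 on match else mu) and zero-cost
// vertex crossings between consecutive edges. States are expanded lazily;
// the product graph is never materialized.

namespace {

struct NtResult {
  bool found = false;
  double cost = 0;
  int end_e = -1, end_o = -1, end_q = 0;
  std::vector<int> edges;
  std::string cigar;
  int nmatch = 0, nmis = 0, nins = 0, ndel = 0;
  int64_t states = 0;
  std::string reason = "";
};

// op codes packed into the low 3 bits of the parent pointer
enum Op { OP_NONE = 0, OP_MATCH = 1, OP_MIS = 2, OP_DEL = 3, OP_INS = 4,
          OP_CROSS = 5 };

struct Searcher {
  const Graph& g;
  const std::string& sub;
  double mu, sigma;
  int64_t qw;  // qlen + 1
  std::vector<char> allowed;

  std::unordered_map<uint64_t, double> dist;
  std::unordered_map<uint64_t, uint64_t> parent;

  Searcher(const Graph& g_, const std::string& sub_, double mu_, double sigma_,
           const IntegerVector& allowed_edges)
      : g(g_), sub(sub_), mu(mu_), sigma(sigma_) {
    qw = static_cast<int64_t>(sub.size()) + 1;
    if (allowed_edges.size() == 0) {
      allowed.assign(g.m, 1);
    } else {
      allowed.assign(g.m, 0);
      for (int i = 0; i < allowed_edges.size(); ++i)
        allowed[allowed_edges[i] - 1] = 1;
    }
  }

  uint64_t key(int e, int o, int q) const {
    return static_cast<uint64_t>(g.posoff[e] + o) * qw + q;
  }
  void decode(uint64_t k, int& e, int& o, int& q) const {
    q = static_cast<int>(k % qw);
    int64_t pos = static_cast<int64_t>(k / qw);
    int lo = 0, hi = g.m;  // find e with posoff[e] <= pos < posoff[e+1]
    while (hi - lo > 1) {
      int mid = (lo + hi) / 2;
      if (g.posoff[mid] <= pos) lo = mid; else hi = mid;
    }
    e = lo;
    o = static_cast<int>(pos - g.posoff[lo]);
  }

  template <typename Push>
  void expand(uint64_t k, double d, Push push) {
    int e, o, q;
    decode(k, e, o, q);
    int L = g.len(e);
    int qlen = static_cast<int>(sub.size());
    if (o < L) {
      if (q < qlen) {
        char gc = g.lab[e][o], qc = sub[q];
        bool match = (gc == qc) && gc != 'N' && gc != 'n' && qc != 'N';
        push(key(e, o + 1, q + 1), d + (match ? 0.0 : mu), k,
             match ? OP_MATCH : OP_MIS);
      }
      push(key(e, o + 1, q), d + sigma, k, OP_DEL);
    } else {
      for (auto& lnk : g.out[e]) {
        if (!allowed[lnk.first]) continue;
        push(key(lnk.first, lnk.second, q), d, k, OP_CROSS);
      }
    }
    if (q < qlen) push(key(e, o, q + 1), d + sigma, k, OP_INS);
  }
};

NtResult run_search(const Graph& g, const std::string& sub, int e1, int o1,
                    int target_e, int target_o, double mu, double sigma,
                    double max_states, int engine,
                    const IntegerVector& allowed_edges) {
  NtResult res;
  Searcher S(g, sub, mu, sigma, allowed_edges);
  int qlen = static_cast<int>(sub.size());
  uint64_t start = S.key(e1, o1, 0);
  uint64_t target = 0;
  bool has_target = target_e >= 0;
  if (has_target) target = S.key(target_e, target_o, qlen);

  S.dist[start] = 0.0;
  S.parent[start] = OP_NONE;
  uint64_t final_key = 0;
  bool done = false;

  auto relax = [&](uint64_t k2, double d2, uint64_t from, int op,
                   auto record) {
    auto it = S.dist.find(k2);
    if (it == S.dist.end() || d2 < it->second) {
      S.dist[k2] = d2;
      S.parent[k2] = (from << 3) | static_cast<uint64_t>(op);
      record(k2, d2);
    }
  };

  auto accept = [&](uint64_t k, int q) {
    if (has_target) return k == target;
    return q == qlen;
  };

  if (engine == 1) {  // 0-1 BFS over unit/zero weights
    std::deque<uint64_t> dq;
    dq.push_back(start);
    while (!dq.empty()) {
      uint64_t k = dq.front();
      dq.pop_front();
      double d = S.dist[k];
      int e, o, q;
      S.decode(k, e, o, q);
      if (accept(k, q)) { final_key = k; done = true; break; }
      if (static_cast<double>(S.dist.size()) > max_states) {
        res.reason = "budget";
        res.states = S.dist.size();
        return res;
      }
      S.expand(k, d, [&](uint64_t k2, double d2, uint64_t from, int op) {
        relax(k2, d2, from, op, [&](uint64_t kk, double dd) {
          if (dd == d) dq.push_front(kk); else dq.push_back(kk);
        });
      });
    }
  } else {  // Dijkstra
    typedef std::pair<double, uint64_t> QE;
    std::priority_queue<QE, std::vector<QE>, std::greater<QE>> pq;
    pq.push({0.0, start});
    while (!pq.empty()) {
      auto [d, k] = pq.top();
      pq.pop();
      auto it = S.dist.find(k);
      if (it == S.dist.end() || it->second < d) continue;
      int e, o, q;
      S.decode(k, e, o, q);
      if (accept(k, q)) { final_key = k; done = true; break; }
      if (static_cast<double>(S.dist.size()) > max_states) {
        res.reason = "budget";
        res.states = S.dist.size();
        return res;
      }
      S.expand(k, d, [&](uint64_t k2, double d2, uint64_t from, int op) {
        relax(k2, d2, from, op,
              [&](uint64_t kk, double dd) { pq.push({dd, kk}); });
      });
    }
  }

  res.states = S.dist.size();
  if (!done) {
    res.reason = "nopath";
    return res;
  }

  res.found = true;
  res.cost = S.dist[final_key];
  int e, o, q;
  S.decode(final_key, e, o, q);
  res.end_e = e;
  res.end_o = o;
  res.end_q = q;

  // trace back ops and the edge sequence
  std::vector<int> ops;
  std::vector<int> cross_edges;
  uint64_t cur = final_key;
  while (true) {
    uint64_t pv = S.parent[cur];
    int op = static_cast<int>(pv & 7);
    if (op == OP_NONE) break;
    if (op == OP_CROSS) {
      int ce, co, cq;
      S.decode(cur, ce, co, cq);
      cross_edges.push_back(ce);
    } else {
      ops.push_back(op);
    }
    cur = pv >> 3;
  }
  std::reverse(ops.begin(), ops.end());
  std::reverse(cross_edges.begin(), cross_edges.end());
  res.edges.push_back(e1);
  for (int ce : cross_edges) res.edges.push_back(ce);

  std::string cigar;
  char prev = 0;
  int runlen = 0;
  auto flush = [&]() {
    if (runlen > 0) cigar += std::to_string(runlen) + prev;
    runlen = 0;
  };
  for (int op : ops) {
    char c;
    switch (op) {
      case OP_MATCH: ++res.nmatch; c = 'M'; break;
      case OP_MIS: ++res.nmis; c = 'M'; break;
      case OP_DEL: ++res.ndel; c = 'D'; break;
      default: ++res.nins; c = 'I'; break;
    }
    if (c != prev) { flush(); prev = c; }
    ++runlen;
  }
  flush();
  res.cigar = cigar;
  return res;
}

List wrap_nt(const NtResult& r) {
  return List::create(
      _["found"] = r.found, _["cost"] = r.cost, _["edges"] = [&] {
        IntegerVector ev(r.edges.size());
        for (size_t i = 0; i < r.edges.size(); ++i) ev[i] = r.edges[i] + 1;
        return ev;
      }(),
      _["end_edge"] = r.end_e + 1, _["end_offset"] = r.end_o,
      _["query_consumed"] = r.end_q, _["cigar"] = r.cigar,
      _["n_match"] = r.nmatch, _["n_mismatch"] = r.nmis, _["n_ins"] = r.nins,
      _["n_del"] = r.ndel, _["states"] = static_cast<double>(r.states),
      _["reason"] = r.reason);
}

}  // namespace

// [[Rcpp::export]]
List cpp_align_fill(List gl, std::string sub, int e1, int o1, int e2, int o2,
                    double mu, double sigma, double max_states, int engine,
                    IntegerVector allowed) {
  Graph g = build_graph(gl);
  NtResult r = run_search(g, sub, e1 - 1, o1, e2 - 1, o2, mu, sigma,
                          max_states, engine, allowed);
  return wrap_nt(r);
}

// [[Rcpp::export]]
List cpp_align_extend(List gl, std::string sub, int e1, int o1, double mu,
                      double sigma, double max_states, int engine,
                      IntegerVector allowed) {
  Graph g = build_graph(gl);
  NtResult r = run_search(g, sub, e1 - 1, o1, -1, -1, mu, sigma, max_states,
                          engine, allowed);
  return wrap_nt(r);
}

// Banded global alignment of query `a` against reference `b` under linear
// gap costs; used to assemble the final cigar of a stitched graph path.
// [[Rcpp::export]]
List cpp_nw_band(std::string a, std::string b, double mu, double sigma,
                 int band) {
  int la = a.size(), lb = b.size();
  int lo = std::min(0, lb - la) - band;       // j - i lower bound
  int hi = std::max(0, lb - la) + band;       // j - i upper bound
  int width = hi - lo + 1;
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> prev(width, INF), curr(width, INF);
  std::vector<uint8_t> tb(static_cast<size_t>(la + 1) * width, 0);
  // ops: 1 match, 2 mismatch, 3 del (consume b), 4 ins (consume a)
  auto at = [&](int i, int diag) -> size_t {
    return static_cast<size_t>(i) * width + (diag - lo);
  };
  for (int j = std::max(0, lo); j <= std::min(lb, hi); ++j) {
    prev[j - lo] = j * sigma;
    if (j > 0) tb[at(0, j)] = 3;
  }
  for (int i = 1; i <= la; ++i) {
    std::fill(curr.begin(), curr.end(), INF);
    int jmin = std::max(0, i + lo), jmax = std::min(lb, i + hi);
    for (int j = jmin; j <= jmax; ++j) {
      int d = j - i;
      double best = INF;
      uint8_t op = 0;
      if (j > 0 && prev[d - lo] < INF) {  // diagonal
        bool m = a[i - 1] == b[j - 1] && a[i - 1] != 'N' && b[j - 1] != 'N';
        double c = prev[d - lo] + (m ? 0.0 : mu);
        if (c < best) { best = c; op = m ? 1 : 2; }
      }
      if (j > 0 && d - 1 >= lo && d - 1 <= hi && curr[d - 1 - lo] < INF) {
        double c = curr[d - 1 - lo] + sigma;  // del: consume b
        if (c < best) { best = c; op = 3; }
      }
      if (d + 1 <= hi && prev[d + 1 - lo] < INF) {
        double c = prev[d + 1 - lo] + sigma;  // ins: consume a
        if (c < best) { best = c; op = 4; }
      }
      curr[d - lo] = best;
      tb[at(i, d)] = op;
    }
    std::swap(prev, curr);
  }
  int dfin = lb - la;
  double cost = (dfin >= lo && dfin <= hi) ? prev[dfin - lo] : INF;
  if (!std::isfinite(cost))
    return List::create(_["found"] = false, _["cost"] = R_PosInf);
  // traceback
  std::string cigar;
  int nmatch = 0, nmis = 0, nins = 0, ndel = 0;
  std::vector<char> ops;
  int i = la, j = lb;
  while (i > 0 || j > 0) {
    uint8_t op = tb[at(i, j - i)];
    if (op == 1 || op == 2) {
      ops.push_back('M');
      if (op == 1) ++nmatch; else ++nmis;
      --i; --j;
    } else if (op == 3) {
      ops.push_back('D'); ++ndel; --j;
    } else if (op == 4) {
      ops.push_back('I'); ++nins; --i;
    } else {
      stop("internal: banded traceback lost");
    }
  }
  std::reverse(ops.begin(), ops.end());
  char prevc = 0;
  int runlen = 0;
  for (char c : ops) {
    if (c != prevc) {
      if (runlen) cigar += std::to_string(runlen) + prevc;
      prevc = c; runlen = 0;
    }
    ++runlen;
  }
  if (runlen) cigar += std::to_string(runlen) + prevc;
  return List::create(_["found"] = true, _["cost"] = cost, _["cigar"] = cigar,
                      _["n_match"] = nmatch, _["n_mismatch"] = nmis,
                      _["n_ins"] = nins, _["n_del"] = ndel);
}
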