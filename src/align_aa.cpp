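#include "graph_core.h"

using namespace Rcpp;

// Frame-state alignment of a protein fragment to the nucleotide graph.
// States are <graph position, query position, frame state>, the frame state
// being a 0-2 base partial codon accumulated while walking edge labels.
// Rules: (1) accumulate a base, zero weight; (2) complete a codon without
// consuming a residue = codon deletion, weight sigma; (3) complete a codon
// and consume a residue, weight C - M[aa(codon), residue]; (4) consume a
// residue without graph movement (insertion), weight C + sigma, only
// between codons (fs = eps); (5) zero-weight vertex crossing, fs preserved
// so codons may span edges. Codons completing to a stop are forbidden.
// The constant C > max(M) makes all weights non-negative (Dijkstra applies);
// every source-to-sink path is shifted by exactly |query| * C.
//
// With rc_codons = TRUE the engine runs on the reverse-complement strand:
// bases are accumulated in reversed order and each completed codon is
// reverse-complemented before translation. This implements leftward
// extension through the forward engine.

namespace {

enum AaOp { A_NONE = 0, A_BASE = 1, A_DELC = 2, A_RES = 3, A_INS = 4,
            A_CROSS = 5 };

struct AaSearch {
  const Graph& g;
  const std::string& q;       // protein fragment
  const NumericMatrix& M;     // substitution scores (higher = better)
  std::vector<int> aa_idx;    // char -> matrix row, -1 unknown
  std::vector<int> q_idx;     // per-residue matrix index
  double sigma, C;
  bool rc_codons, allow_stop_del;
  int64_t qw;
  std::vector<char> allowed;

  std::unordered_map<uint64_t, double> dist;
  std::unordered_map<uint64_t, uint64_t> parent;

  AaSearch(const Graph& g_, const std::string& q_, const NumericMatrix& M_,
           const std::string& alphabet, double sigma_, double C_,
           bool rc_codons_, bool allow_stop_del_,
           const IntegerVector& allowed_edges)
      : g(g_), q(q_), M(M_), sigma(sigma_), C(C_), rc_codons(rc_codons_),
        allow_stop_del(allow_stop_del_) {
    qw = static_cast<int64_t>(q.size()) + 1;
    aa_idx.assign(256, -1);
    for (size_t i = 0; i < alphabet.size(); ++i)
      aa_idx[static_cast<unsigned char>(alphabet[i])] = static_cast<int>(i);
    q_idx.resize(q.size());
    for (size_t i = 0; i < q.size(); ++i) {
      int ix = aa_idx[static_cast<unsigned char>(q[i])];
      if (ix < 0) stop("residue '%c' not in the substitution matrix", q[i]);
      q_idx[i] = ix;
    }
    if (allowed_edges.size() == 0) {
      allowed.assign(g.m, 1);
    } else {
      allowed.assign(g.m, 0);
      for (int i = 0; i < allowed_edges.size(); ++i)
        allowed[allowed_edges[i] - 1] = 1;
    }
  }

  // fs codes: 0 = eps; 1+b single base; 6 + b1*5 + b2 pair (b in 0..4, 4 = N)
  uint64_t key(int e, int o, int qp, int fs) const {
    return (static_cast<uint64_t>(g.posoff[e] + o) * 31 + fs) * qw + qp;
  }
  void decode(uint64_t k, int& e, int& o, int& qp, int& fs) const {
    qp = static_cast<int>(k % qw);
    uint64_t rest = k / qw;
    fs = static_cast<int>(rest % 31);
    int64_t pos = static_cast<int64_t>(rest / 31);
    int lo = 0, hi = g.m;
    while (hi - lo > 1) {
      int mid = (lo + hi) / 2;
      if (g.posoff[mid] <= pos) lo = mid; else hi = mid;
    }
    e = lo;
    o = static_cast<int>(pos - g.posoff[lo]);
  }

  char codon_aa(int b1, int b2, int b3) const {
    if (rc_codons) {
      auto cb = [](int b) { return b > 3 ? 4 : 3 - b; };
      return translate_codon(cb(b3), cb(b2), cb(b1));
    }
    return translate_codon(b1, b2, b3);
  }

  template <typename Push>
  void expand(uint64_t k, double d, Push push) {
    int e, o, qp, fs;
    decode(k, e, o, qp, fs);
    int L = g.len(e);
    int qlen = static_cast<int>(q.size());
    int fslen = fs == 0 ? 0 : (fs <= 5 ? 1 : 2);
    if (o < L) {
      int b = base_code(g.lab[e][o]);
      if (fslen < 2) {  // rule 1: accumulate
        int fs2 = fslen == 0 ? 1 + b : 6 + (fs - 1) * 5 + b;
        push(key(e, o + 1, qp, fs2), d, k, A_BASE);
      } else {
        int b1 = (fs - 6) / 5, b2 = (fs - 6) % 5;
        char aa = codon_aa(b1, b2, b);
        bool stop_cod = is_stop_aa(aa);
        if (!stop_cod || allow_stop_del)  // rule 2: codon deletion
          push(key(e, o + 1, qp, 0), d + sigma, k, A_DELC);
        if (!stop_cod && qp < qlen) {     // rule 3: consume residue
          int ai = aa_idx[static_cast<unsigned char>(aa)];
          double w = (ai < 0) ? C + sigma  // unknown translation: as bad as gap
                              : C - M(ai, q_idx[qp]);
          push(key(e, o + 1, qp + 1, 0), d + w, k, A_RES);
        }
      }
    } else {  // rule 5: crossing
      for (auto& lnk : g.out[e]) {
        if (!allowed[lnk.first]) continue;
        push(key(lnk.first, lnk.second, qp, fs), d, k, A_CROSS);
      }
    }
    if (fs == 0 && qp < qlen)  // rule 4: insertion between codons
      push(key(e, o, qp + 1, 0), d + C + sigma, k, A_INS);
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_align_aa(List gl, std::string subp, int e1, int o1, int target_e,
                  int target_o, NumericMatrix M, std::string alphabet,
                  double sigma, double C, bool rc_codons, bool allow_stop_del,
                  double max_states, IntegerVector allowed) {
  Graph g = build_graph(gl);
  AaSearch S(g, subp, M, alphabet, sigma, C, rc_codons, allow_stop_del,
             allowed);
  --e1;
  bool has_target = target_e > 0;
  uint64_t start = S.key(e1, o1, 0, 0);
  uint64_t target = has_target ? S.key(target_e - 1, target_o,
                                       static_cast<int>(subp.size()), 0)
                               : 0;
  int qlen = static_cast<int>(subp.size());

  S.dist[start] = 0.0;
  S.parent[start] = A_NONE;
  typedef std::pair<double, uint64_t> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE>> pq;
  pq.push({0.0, start});
  bool done = false;
  uint64_t final_key = 0;
  std::string reason;
  while (!pq.empty()) {
    auto [d, k] = pq.top();
    pq.pop();
    auto it = S.dist.find(k);
    if (it == S.dist.end() || it->second < d) continue;
    int e, o, qp, fs;
    S.decode(k, e, o, qp, fs);
    bool ok = has_target ? (k == target) : (qp == qlen && fs == 0);
    if (ok) { final_key = k; done = true; break; }
    if (static_cast<double>(S.dist.size()) > max_states) {
      reason = "budget";
      break;
    }
    S.expand(k, d, [&](uint64_t k2, double d2, uint64_t from, int op) {
      auto it2 = S.dist.find(k2);
      if (it2 == S.dist.end() || d2 < it2->second) {
        S.dist[k2] = d2;
        S.parent[k2] = (from << 3) | static_cast<uint64_t>(op);
        pq.push({d2, k2});
      }
    });
  }

  if (!done) {
    if (reason.empty()) reason = "nopath";
    return List::create(_["found"] = false, _["reason"] = reason,
                        _["states"] = static_cast<double>(S.dist.size()));
  }

  int e, o, qp, fs;
  S.decode(final_key, e, o, qp, fs);
  std::vector<int> cross_edges;
  int n_res = 0, n_delc = 0, n_ins = 0;
  uint64_t cur = final_key;
  std::vector<int> ops;
  while (true) {
    uint64_t pv = S.parent[cur];
    int op = static_cast<int>(pv & 7);
    if (op == A_NONE) break;
    if (op == A_CROSS) {
      int ce, co, cq, cf;
      S.decode(cur, ce, co, cq, cf);
      cross_edges.push_back(ce);
    } else {
      if (op == A_RES) ++n_res;
      else if (op == A_DELC) ++n_delc;
      else if (op == A_INS) ++n_ins;
      ops.push_back(op);
    }
    cur = pv >> 3;
  }
  std::reverse(cross_edges.begin(), cross_edges.end());
  std::vector<int> edges{e1};
  for (int ce : cross_edges) edges.push_back(ce);
  IntegerVector ev(edges.size());
  for (size_t i = 0; i < edges.size(); ++i) ev[i] = edges[i] + 1;

  return List::create(
      _["found"] = true, _["weight"] = S.dist[final_key], _["edges"] = ev,
      _["end_edge"] = e + 1, _["end_offset"] = o,
      _["n_res"] = n_res, _["n_del_codons"] = n_delc, _["n_ins"] = n_ins,
      _["nt_consumed"] = 3 * (n_res + n_delc),
      _["states"] = static_cast<double>(S.dist.size()),
      _["reason"] = "");
}

// Maximal exact amino-acid runs between query and target proteins, found by
// 4-mer seeding and bidirectional extension; used for protein anchor search
// on six-frame translated edge labels.
// [[Rcpp::export]]
IntegerMatrix cpp_exact_aa_runs(std::string query, std::string target,
                                int min_len) {
  const int K = 4;
  std::vector<std::pair<int, int>> runs;  // (qs, ts) of maximal runs, len via set
  std::unordered_map<std::string, std::vector<int>> qk;
  int lq = query.size(), lt = target.size();
  if (lq >= K && lt >= K) {
    for (int i = 0; i + K <= lq; ++i) qk[query.substr(i, K)].push_back(i);
    std::unordered_set<int64_t> seen;  // diag * big + qs of run start
    std::vector<std::array<int, 3>> out;
    for (int j = 0; j + K <= lt; ++j) {
      auto it = qk.find(target.substr(j, K));
      if (it == qk.end()) continue;
      for (int i : it->second) {
        int qs = i, ts = j;
        while (qs > 0 && ts > 0 && query[qs - 1] == target[ts - 1]) {
          --qs; --ts;
        }
        int64_t sig = static_cast<int64_t>(i - j) * 1000000 + qs;
        if (seen.count(sig)) continue;
        seen.insert(sig);
        int qe = i + K, te = j + K;
        while (qe < lq && te < lt && query[qe] == target[te]) { ++qe; ++te; }
        if (qe - qs >= min_len) out.push_back({qs, qe, ts});
      }
    }
    IntegerMatrix res(out.size(), 3);
    for (size_t r = 0; r < out.size(); ++r) {
      res(r, 0) = out[r][0];
      res(r, 1) = out[r][1];
      res(r, 2) = out[r][2];
    }
    colnames(res) = CharacterVector::create("qs", "qe", "ts");
    return res;
  }
  IntegerMatrix res(0, 3);
  colnames(res) = CharacterVector::create("qs", "qe", "ts");
  return res;
}
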