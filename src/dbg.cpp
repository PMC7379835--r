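#include "graph_core.h"

using namespace Rcpp;

// Node-centric compacted de Bruijn graph over the canonical k-mers of the
// input sequences. Unitigs (maximal non-branching paths) become segments;
// adjacent segments overlap by k-1 bp. Segment ids are assigned by
// lexicographic order of the canonical segment sequence, which makes the
// construction deterministic.

namespace {

struct Dbg {
  int k;
  uint64_t mask;
  std::unordered_set<uint64_t> kmers;  // canonical

  uint64_t rc(uint64_t x) const {
    uint64_t r = 0;
    for (int i = 0; i < k; ++i) {
      r = (r << 2) | (3 - (x & 3));
      x >>= 2;
    }
    return r;
  }
  uint64_t canon(uint64_t x) const { return std::min(x, rc(x)); }
  bool has(uint64_t x) const { return kmers.count(canon(x)) > 0; }

  int succs(uint64_t x, uint64_t out[4]) const {
    int n = 0;
    for (uint64_t c = 0; c < 4; ++c) {
      uint64_t y = ((x << 2) & mask) | c;
      if (has(y)) out[n++] = y;
    }
    return n;
  }
  int preds(uint64_t x, uint64_t out[4]) const {
    int n = 0;
    for (uint64_t c = 0; c < 4; ++c) {
      uint64_t y = (x >> 2) | (c << (2 * (k - 1)));
      if (has(y)) out[n++] = y;
    }
    return n;
  }
  std::string decode(uint64_t x) const {
    std::string s(k, 'A');
    static const char B[] = "ACGT";
    for (int i = k - 1; i >= 0; --i) {
      s[i] = B[x & 3];
      x >>= 2;
    }
    return s;
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_build_dbg(std::vector<std::string> seqs, int k) {
  if (k < 11 || k > 31 || k % 2 == 0) stop("k must be odd and in 11..31");
  Dbg D;
  D.k = k;
  D.mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (const auto& s : seqs) {
    if (static_cast<int>(s.size()) < k) continue;
    uint64_t v = 0;
    int run = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      int b = base_code(s[i]);
      if (b > 3) { run = 0; v = 0; continue; }
      v = ((v << 2) | static_cast<uint64_t>(b)) & D.mask;
      if (++run >= k) D.kmers.insert(D.canon(v));
    }
  }
  if (D.kmers.empty()) stop("no k-mers: input shorter than k?");

  std::unordered_set<uint64_t> visited;  // oriented k-mers
  std::vector<std::string> unitigs;
  uint64_t nb[4];

  auto is_start = [&](uint64_t x) {
    if (D.preds(x, nb) != 1) return true;
    uint64_t p = nb[0];
    uint64_t tmp[4];
    return D.succs(p, tmp) != 1;
  };
  // Each *oriented* maximal unitig is walked once; forward and
  // reverse-complement copies are collapsed afterwards by canonical sequence.
  auto walk = [&](uint64_t x) {
    std::string seq = D.decode(x);
    visited.insert(x);
    uint64_t cur = x;
    while (true) {
      if (D.succs(cur, nb) != 1) break;
      uint64_t y = nb[0];
      uint64_t tmp[4];
      if (D.preds(y, tmp) != 1) break;
      if (visited.count(y)) break;  // cycle closure
      visited.insert(y);
      static const char B[] = "ACGT";
      seq.push_back(B[y & 3]);
      cur = y;
    }
    unitigs.push_back(seq);
  };

  std::vector<uint64_t> all;
  all.reserve(D.kmers.size());
  for (uint64_t x : D.kmers) all.push_back(x);
  std::sort(all.begin(), all.end());
  for (uint64_t cx : all) {
    for (uint64_t x : {cx, D.rc(cx)}) {
      if (visited.count(x)) continue;
      if (is_start(x)) walk(x);
    }
  }
  for (uint64_t cx : all) {  // leftover pure cycles
    for (uint64_t x : {cx, D.rc(cx)}) {
      if (!visited.count(x)) walk(x);
    }
  }

  // canonicalize and sort segments
  std::vector<std::string> segs;
  segs.reserve(unitigs.size());
  for (auto& u : unitigs) {
    std::string r = revcomp_str(u);
    segs.push_back(u <= r ? u : r);
  }
  std::sort(segs.begin(), segs.end());
  segs.erase(std::unique(segs.begin(), segs.end()), segs.end());
  int n = segs.size();

  // map oriented first k-mers of segments
  std::unordered_map<uint64_t, std::pair<int, int>> start_of;  // kmer -> (seg, or)
  for (int i = 0; i < n; ++i) {
    uint64_t f = 0, fr = 0;
    std::string r = revcomp_str(segs[i]);
    for (int j = 0; j < k; ++j) {
      f = (f << 2) | static_cast<uint64_t>(base_code(segs[i][j]));
      fr = (fr << 2) | static_cast<uint64_t>(base_code(r[j]));
    }
    start_of[f] = {i, 0};
    if (fr != f) start_of[fr] = {i, 1};
  }

  std::vector<std::array<int, 5>> links;  // from, fromor, to, toor, ov
  for (int i = 0; i < n; ++i) {
    for (int ori = 0; ori < 2; ++ori) {
      std::string s = ori == 0 ? segs[i] : revcomp_str(segs[i]);
      uint64_t last = 0;
      for (int j = static_cast<int>(s.size()) - k;
           j < static_cast<int>(s.size()); ++j)
        last = (last << 2) | static_cast<uint64_t>(base_code(s[j]));
      int ns = D.succs(last, nb);
      for (int t = 0; t < ns; ++t) {
        auto it = start_of.find(nb[t]);
        if (it == start_of.end()) stop("internal: successor k-mer is not a segment start");
        links.push_back({i + 1, ori, it->second.first + 1, it->second.second,
                         k - 1});
      }
    }
  }

  CharacterVector seg_out(n);
  for (int i = 0; i < n; ++i) seg_out[i] = segs[i];
  int nl = links.size();
  IntegerVector lf(nl), lt(nl), lov(nl);
  CharacterVector lfo(nl), lto(nl);
  for (int i = 0; i < nl; ++i) {
    lf[i] = links[i][0];
    lfo[i] = links[i][1] == 0 ? "+" : "-";
    lt[i] = links[i][2];
    lto[i] = links[i][3] == 0 ? "+" : "-";
    lov[i] = links[i][4];
  }
  return List::create(_["segments"] = seg_out, _["link_from"] = lf,
                      _["link_from_orient"] = lfo, _["link_to"] = lt,
                      _["link_to_orient"] = lto, _["link_overlap"] = lov);
}
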