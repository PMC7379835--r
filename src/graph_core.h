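#pragma once

#include <Rcpp.h>
#include <cstdint>
#include <deque>
#include <queue>
#include <string>
#include <unordered_map>
#include <unordered_set>
#include <vector>

// Oriented-edge view of an assembly graph as passed from R:
// labels[i] is the nucleotide label of edge i (0-based here, 1-based in R),
// rc[i] its reverse-complement partner, out/in adjacency carries the link
// overlap in bp (the prefix of the successor duplicated at the junction).
struct Graph {
  int m = 0;
  std::vector<std::string> lab;
  std::vector<int> rc;
  std::vector<std::vector<std::pair<int, int>>> out;  // (to, overlap)
  std::vector<std::vector<std::pair<int, int>>> in;   // (from, overlap)
  std::vector<int64_t> posoff;  // prefix sums of (len+1): global position ids
  int64_t total_pos = 0;

  int len(int e) const { return static_cast<int>(lab[e].size()); }
};

Graph build_graph(const Rcpp::List& gl);

inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    case 'a': return 't';
    case 'c': return 'g';
    case 'g': return 'c';
    case 't': return 'a';
    default: return 'N';
  }
}

inline std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

// base codes: A=0 C=1 G=2 T=3, anything else (N) = 4
inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;
  }
}

// standard genetic code; codon index = c1*16 + c2*4 + c3 over ACGT;
// any codon containing an ambiguous base translates to 'X'
char translate_codon(int b1, int b2, int b3);
inline bool is_stop_aa(char aa) { return aa == '*'; }
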