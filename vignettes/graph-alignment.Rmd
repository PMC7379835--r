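---
title: "Aligning long nucleotide and protein sequences to assembly graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning long nucleotide and protein sequences to assembly graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its method: the model and its
assumptions, the parameters that matter, the numerical choices, what the
built-in simulator does and does not emulate, and the known limitations.

## The model

An assembly graph is a directed graph whose edges carry nucleotide labels;
every segment is present in both orientations, and a link `A+ -> B+` is
mirrored as `B- -> A-`, so reverse-strand queries need no special casing.
Positions sit *between* characters (0-based, half-open ranges throughout);
a graph position is a pair (edge, offset) with offset in `[0, |e|]`. The
label of a path concatenates edge labels, trimming each successor's prefix
by the link overlap — unlike the usual idealization that ignores unitig
overlaps, this makes `label_of_path()` exact on real SPAdes-style GFA where
adjacent edges share k−1 bp.

The semi-global alignment of a query *S* is a path *P* minimizing the
linear-gap alignment cost of *Label(P)* against *S* over all paths, with
mismatch cost μ ≥ 0 and per-base gap cost σ ≥ 0 (defaults μ = σ = 1, i.e.
edit distance). Affine gaps are out of scope.

## Search over the implicit alignment graph

Fragment alignment is cast as single-source shortest path in the alignment
(edit) graph: vertices ⟨p, j⟩ for every graph position p and fragment
position j; deletion edges ⟨p,j⟩→⟨p′,j⟩ of weight σ; insertion edges
⟨p,j⟩→⟨p,j+1⟩ of weight σ; diagonal edges of weight 0 on match and μ
otherwise; and zero-weight crossing edges joining the end of one edge to
the overlap offset of its successors. All weights are non-negative, so
Dijkstra finds minimum-weight paths; the graph is expanded lazily (states
are hashed on demand and never materialized), and the search stops at the
first accepted state — the fixed target ⟨p₂, |Sub|⟩ for filling paths, or
any state with j = |Sub| for terminal extensions. Leftward extension runs
the same engine on the reverse-complement strand with the reversed
fragment and maps the result back.

When μ = σ = 1 every edge weighs 0 or 1 and a double-ended queue replaces
the priority queue (0-1 BFS): zero-weight relaxations go to the front,
unit-weight ones to the back. Both engines return the same optimum — this
is asserted, not assumed — and the 0-1 variant runs in O(|G|·|Sub|).

Numerical and tie-breaking choices:

* Equal-cost states pop in deterministic key order, and neighbors are
  generated diagonal → deletion → crossing → insertion, so cigars are
  reproducible across runs.
* Each sub-search carries a state budget (default 5·10⁶). Exhaustion is a
  *bounded-search failure*: the caller keeps the largest contiguous part of
  the anchor skeleton and reports reduced coverage rather than guessing.
* Each filling/extension sub-search is restricted to the neighborhood of
  its endpoints within radius α·|fragment| + 2t bp. Chaining guarantees the
  connecting path fits within α times the query gap, so the restriction is
  exact for the paths the skeleton promises; it only prunes pathological
  detours.
* `N` never matches anything (mismatch cost applies): conservative handling
  of ambiguous bases.

## Anchors, filtering, chaining

Anchor search replaces an external local aligner with a self-contained
seeder: exact k-mer matches (seed size 14 bp, the sensitivity-oriented
setting for long diverged queries) are merged per diagonal into maximal
exact runs, and colinear runs on the same edge are chained into gapped
anchors when the query and edge gaps are below 150 bp and their diagonal
drift stays within max(15, 0.35·gap). At a 10% error rate exact seeds occur
every ~4 bp on average, so a read still produces one long anchor per edge
it traverses. Anchors discovered below the graph's de Bruijn k (or the
seed size, when k is unknown) are discarded. External seeders remain
pluggable through PAF import, which feeds the identical filtering path.

Filtering applies three rules **in order**: (1) anchors in the middle of
long edges — where the inequality
`(ee−es) + min(qs, es) + min(|S|−qe, |e|−ee) > 3(ee−es)` holds — are
discarded when they span less than T = 500 bp; (2) anchors at least half of
whose query range is covered by other anchors are discarded; (3) anchors
spanning less than t = 200 bp are discarded. Rule 2 as printed would drop
*both* members of a mutually-covering pair; this implementation resolves
such sets by a worst-first sweep (ascending span, larger edge id first)
that re-checks coverage against the anchors still alive, so exactly one
representative — the largest span, ties to the smallest edge id — survives.
That choice preserves sensitivity on perfectly duplicated sequence and is
deliberately documented here as a deviation from the strictest reading.

Chaining maximizes total anchor span over chains whose consecutive anchors
are compatible: `b` follows `a` on the query without overlap and the
minimal graph distance from (e(a), ee) to (e(b), es) is at most α times the
query gap, α = 1.3. The distance query is capped at α·gap, which suffices
to decide the predicate; a zero query gap requires zero graph distance.
The printed form of the predicate in the source material has the
inequality inverted relative to its prose ("does not significantly
exceed"); this implementation follows the prose. Ties between equal-weight
chains fall to the smaller accumulated graph distance, then the
lexicographically smallest index sequence.

After filling and extension the stitched path is re-scored end-to-end
against the covered query range by a banded global alignment (band doubled
until the optimum is provably inside), so mismatches inside anchors —
which the skeleton trusts as near-exact — are still reflected exactly in
the final cost, cigar and identity. Terminal pure-insertion runs (query
tails consumed off the end of a path, e.g. at graph dead ends) are trimmed
from the reported range: they carry no graph alignment and should not
count as coverage. A query is *mapped* when one path covers ≥ 80% of it;
identity is matches over alignment columns.

## Protein mode

A path is an *AA-path* if its label translates, in frame, to a protein
without stop codons; protein alignment minimizes cost between the query
and the translation of an AA-path. The alignment graph gains a frame
state: vertices ⟨p, j, fs⟩ with fs a partial codon of 0–2 bases. Five edge
rules: accumulate a base (weight 0, |fs| < 2); complete a codon without
consuming a residue (codon deletion, weight σ); complete a codon and
consume a residue (weight −M[Translate(fs+base), residue]); insert a
residue without graph movement (weight σ, only at fs = ε, so graph-side
gaps are codon-aligned); and zero-weight vertex crossings that preserve
fs, letting codons span edges. Completing a stop codon is forbidden for
both deletion and match rules — a flag can re-allow deleted stops for
pseudo-gene hunting, off by default. Defaults: BLOSUM90 (bundled in NCBI
text format, along with BLOSUM62) and σ = 5.

Because substitution scores are maximized, the search uses costs −M, which
are negative for good matches; every query-consuming edge (match and
insertion rules) is therefore shifted by a constant C > max(M). All
source-to-sink paths contain exactly |query| such edges, so every path
weight shifts by |query|·C and the argmin is unchanged, while all weights
become non-negative and Dijkstra applies. The sink is any state
⟨p, |query|, ε⟩: terminating with an empty frame state keeps the consumed
nucleotide count a multiple of three and matches the exactly-|query|
counting in the shift argument. Shift invariance over
C ∈ {max(M)+1, max(M)+10, 10·max(M)} is asserted in the tests.

Protein anchors are ungapped exact amino-acid runs between the query and
six-frame translations of edge labels (three frames per orientation; the
doubled graph supplies the reverse strand) — the nucleotide-level view of
this is matching canonical codon encodings with an infinite gap-open
penalty, and exactness per residue is what frame consistency demands.
Anchors shorter than the graph k (floor: 5 codons) are discarded; there is
no chaining — proteins are short enough that extending each anchor both
ways is simpler and dodges cross-anchor frame coordination. Left
extensions run on the reverse-complement strand with the reversed query
prefix, frame states acting as codon suffixes: each completed codon is
reverse-complemented before translation. Paths covering less than 80% of
the query coding length (3·|query| nt) are dropped, identical paths
deduplicated, and survivors are translated and re-scored with
`Biostrings::pairwiseAlignment` (global, the same matrix, linear gap σ) —
the reported score and identity come from that re-alignment, while the
engine's own un-shifted weight provides an independent cross-check in the
test suite.

## The simulator, and what passing tests mean

`simulation_config()` defaults *are* the study conditions used by the
acceptance checks: a 100 kb random genome (k = 21) with two repeat
families planted twice each at 500 bp and 97% identity — enough shared
21-mers to branch the graph realistically — plus 20 planted ORFs of
100–300 codons (start codon, stop-free body, terminal stop); 200 reads of
2–5 kb from either strand under a per-base error process of 6%
mismatches, 2% insertions, 2% deletions (a long-read-like, 10% total
rate); and query proteins point-mutated at 10% per residue (~90%
amino-acid identity, matching the similarity regime the protein mode
targets). Graph construction is node-centric compaction over canonical
k-mers with deterministic ids, and every genome substring maps to a unique
path that `trace_path()` recovers — the ground truth for round-trip tests.

The error process draws independently per base, so it does not emulate
homopolymer-length biases, chimeras or quality-correlated error bursts of
real ONT/PacBio data, and the random genome lacks the skewed composition
and long tandem arrays of real bacteria. Passing the round-trip checks
therefore demonstrates algorithmic correctness (anchoring through optimal
path search) under realistic error *rates*, not end-to-end performance on
any particular instrument's artefacts.

Problem sizes in the test suite were chosen to exercise every stage at
meaningful scale while keeping a laptop-friendly runtime: oracle
equivalence on hundreds of random instances (explicit Bellman–Ford product
graphs up to 8 edges × 30 bp fragments; 500 single-edge string pairs
against classical DP; 300 exhaustive chaining instances with n ≤ 10), and
the full 100 kb / 200-read / 20-ORF round trip.

## Degenerate inputs and edge cases

Empty fragments are legal everywhere (cost 0 at coincident endpoints);
empty query files produce zero-row outputs, not errors; queries with no
surviving anchors are reported unaligned; an unreachable filling target is
a bounded-search failure that degrades to the best contiguous skeleton. A
segment that equals its own reverse complement is kept as two edges whose
labels coincide. GFA links with `*` overlaps are read as 0; malformed
lines fail loudly with their line number.

## Limitations

Affine gap penalties, split-read alignments, frameshift-tolerant protein
alignment (single-base indels inside codons) and base-quality-aware
scoring are out of scope. The de Bruijn builder encodes k-mers in 64-bit
words, restricting construction to odd k ≤ 31 (alignment itself accepts
any GFA overlaps). Protein mode reports the best-scoring paths it
extended; it does not enumerate co-optimal gene variants.
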