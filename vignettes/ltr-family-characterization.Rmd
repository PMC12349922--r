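---
title: "Characterizing LTR retrotransposon families: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing LTR retrotransposon families: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltrfam)
```

`ltrfam` picks up where intact-element predictors stop: given
LTR_retriever-style predictions and the genome, it groups elements into
families, assigns REXdb clades, dates insertions, and quantifies
per-copy expression. This vignette explains the models behind each
stage, the parameters that matter, and the choices made where the
design was genuinely open.

## Family clustering

LTR-RT families are conventionally defined by clustering LTR sequences
at 80 % identity. We cluster **5′ LTRs only**: the two LTRs of an
element are near-identical, so adding 3′ LTRs doubles the work without
adding information, and the 5′ LTR is the conventional proxy for the
element.

The algorithm reproduces cd-hit-est's greedy incremental semantics
rather than wrapping the binary:

1. sort sequences by length descending (ties by id, so runs are
   bit-reproducible);
2. each sequence joins the **first** existing cluster whose
   representative aligns with identity ≥ `c` (default 0.8) and with the
   alignment covering ≥ `aL` (default 0.8) of the representative;
3. otherwise it founds a new cluster and becomes its representative.

Identity is alignment-column identity of the best local alignment
(match +2, mismatch −3, gap open −5, gap extend −2; a gap of length L
costs 5 + 2L). Because sequences are processed longest-first, the
representative is always the longer sequence of any comparison, so
`aL`-coverage of the representative matches cd-hit's definition of
`-aL`. Two deliberate departures from the cd-hit binary: we do not
reproduce its k-mer prefilter heuristics (exact dynamic programming is
affordable at the scale of intact-element sets, and removes a source of
order-dependent approximation), and the emitted "consensus" is the
cluster seed — which is also what cd-hit actually outputs, despite the
word consensus being in common use for it.

Families are renamed `FAM_<n>` in size order (ties by representative
length, then id), and the seed sequences form the masking library
(`FAM_n#LTR`).

## Copy number, coverage and the masking stand-in

Per family, **copy number counts hit rows** — the way repeat annotators
report copies; fragmented alignments therefore inflate it, which is
documented rather than corrected. **Coverage** is the length of the
union of the family's hit intervals per chromosome; genome-wide totals
additionally union across families, so nested and overlapping
annotations never double-count. The genome-wide LTR percentage is
always computed from the pooled union, never by summing per-family
percentages.

Hits normally come from a RepeatMasker `.out` file
(`read_repeatmasker_out` understands the dialect: three header lines,
`C` for minus strand, `#class` suffixes stripped). For self-contained
runs, `naive_mask` is a desk-scale stand-in: each library sequence is
scanned against both strands allowing substitutions only, and hits with
identity ≥ 0.8 and length ≥ 100 bp are kept greedily by score without
overlap. Those defaults mirror the clustering threshold; the scan is a
testing device for small genomes, not a masker for real ones (no
indels, no scoring matrices, no overlap-resolution policy).

## Clade assignment by path overlap

Within superfamilies, plant LTR-RTs fall into REXdb clades (Ale, Tork,
Ikeros, TAR, Ivana, SIRE in Ty1/Copia; Galadriel, Reina, CRM, Tekay,
Athila in Ty3/Gypsy), defined by reverse-transcriptase phylogeny. The
pipeline extracts each element's longest ORF (ATG→stop, all six frames,
ties broken by frame order +1,+2,+3,−1,−2,−3 then leftmost; the stop is
required, so a start codon running off the sequence end does not
qualify), aligns it to clade-tagged markers (local alignment, BLOSUM62,
gap −11/−1, raw-score threshold 50 in place of an e-value), and the
resulting RT domains go to external alignment and tree inference
(mafft/fasttree class tools). Tree building is out of scope here; the
classifier consumes the resulting Newick.

The classifier itself:

- a from-scratch Newick parser (branch lengths, internal labels,
  quoted labels) stored in flat vectors; parsing and traversal use
  explicit stacks, never recursion, so the current root-to-node path is
  the only state held (O(height) space) and 10,000-node caterpillar
  trees traverse without recursion-depth failures;
- root-to-marker paths are collected for every leaf whose label matches
  the marker pattern (default `#<clade>$` over the 11-clade
  vocabulary; purely numeric labels are support values, never markers);
- for each non-marker leaf, the overlap with a marker is the longest
  common **prefix** of their root-anchored paths — equivalently the
  depth of their most recent common ancestor plus one. Prefix overlap
  is the only overlap notion consistent with collecting root-anchored
  paths in the first place. The marker with maximal overlap supplies
  the clade.

Two rules the overlap notion alone does not fix:

- **Ties** are broken toward the deeper marker path, then the
  lexicographically smallest marker label. Deeper placement is more
  specific; the second key just makes runs deterministic. No biological
  claim is attached to the tie-break.
- **Unclassified:** a query whose best overlap is 1 shares only the
  root with every marker — the tree offers no evidence — so it is
  reported `unclassified` (threshold `min_overlap`, configurable).

Branch lengths are parsed but ignored: the classification is purely
topological, which makes it robust to rate variation but blind to a
short-branch query sitting next to a long-branch marker.

## Expression quantification

From a sorted SAM file (text; BAM is out of scope), each record's
reference span comes from its CIGAR (M/=/X/D consume reference, N
splits the span, I/S/H do not). A fragment — a read name; a pair is one
fragment — is compatible with an element when ≥ 50 % of an alignment's
span lies inside the element. The 50 % rule is a robustness choice for
boundary-straddling reads (configurable); compatibility is the union
over a fragment's records, so secondary alignments make multimappers
multiply compatible.

Ambiguous fragments are fractionally reassigned by EM on a
uniform-prior mixture: initialize each k-way ambiguous fragment at 1/k;
E-step weights proportional to current abundance (count/length); M-step
sums weights; stop when the largest count change is below `tol` (1e-6)
or at 100 iterations. Total counts are conserved at every iteration by
construction, and the iteration trace is exposed for verification. This
is a deliberately simple reassignment model — the full Bayesian
treatment of reassignment priors found in dedicated TE-expression tools
is not reproduced — but it has the fixed points that matter: unique
reads are untouched, one-sided ambiguity drains to the supported locus,
and symmetric ambiguity splits evenly.

FPKM = fragments × 10⁹ / (length × total mapped fragments), where the
total counts all mapped fragments (including element-incompatible
ones). The same fragment-based number is sometimes printed as RPKM for
single-end data; the output column is always `fpkm`. "Expressed" means
≥ 1 assigned fragment by default — an arbitrary but reported threshold;
both EM counts and unique-only counts are emitted so either convention
can be applied downstream.

## Insertion-time dating

The two LTRs are identical on insertion and diverge neutrally, so
inter-LTR divergence dates the insertion. With d = 1 − identity,
K = −¾·ln(1 − 4d/3) (Jukes–Cantor) and T = K/(2μ), default
μ = 1.3 × 10⁻⁸ substitutions/site/year — the rate conventionally used
for plant LTR dating (configurable; halving μ doubles every age).
Times stated in the prediction table take precedence; the formula is
the fallback, and d ≥ 0.75 is refused (outside the JC domain).
"Dominant" (burst) families are operationalized as the smallest set of
top-ranked families holding 50 % of coverage (or of intact elements —
both metrics are supported since both conventions appear in practice),
alongside per-family median and IQR of insertion times. No attempt is
made to segment bursts into time windows.

## The synthetic generator: what it emulates, what it does not

`make_toy_genome` plants, per family, copies of an ancestral
LTR–internal–LTR element into random background sequence. Each copy
diverges from its ancestor at `sub_rate` (default 0.05 — comfortably
within one 80 %-identity family while keeping independent families
unrelated), and its two LTRs then diverge from each other at a
per-copy age rate drawn uniformly in [0, `sub_rate`], so measured
inter-LTR identities vary like insertion ages do. `sub_rate = 0` is the
noiseless limit: all copies identical. Defaults (4 families × 10
copies, 400 bp LTRs, 3 kb internal) keep a full pipeline run in
seconds. The mutation model is substitution-only by default (indels via
`indel_rate` are restricted to internal regions); `simulate_reads`
emits error-free single-end reads uniformly within elements, with
secondary records at equal offsets in near-identical (≥ 98 %) family
copies.

What passing tests on these fixtures therefore show: the clustering,
coverage, classification, EM and dating machinery is correct under
clean, well-separated conditions. What they do not show: behavior under
nested/fragmented insertions, solo LTRs, sequencing error, indel-rich
divergence, or families straddling the 80 % boundary — real-data
phenomena the generator deliberately omits. One integer seed drives one
private RNG stream per generator call (callers' RNG state is restored),
so every fixture is byte-reproducible.

## Numerical and scale choices

Problem sizes in the test suite are chosen to exercise the algorithms,
not the hardware: clustering fixtures of 40–50 sequences, classifier
checks on 200 random trees of 10–500 leaves against a brute-force MRCA
oracle, 300 random 2-kb sequences against a six-frame ORF oracle, 100
random hit sets against a per-base coverage oracle. Exact dynamic
programming limits clustering to desk-scale inputs (thousands of LTRs);
the greedy pass is quadratic in cluster count times sequence length.
Degenerate inputs are contracts, not surprises: empty pass.list files
parse to empty tables, an all-marker tree classifies nothing, a
zero-length element is an FPKM error, all-zero cluster metrics refuse a
cumulative curve, and cumulative curves end at exactly 1.0 by
construction. The declared `threads` setting is recorded in the run
manifest but does not alter any result: every reduction in the pipeline
is order-independent, so parallel and serial execution are
interchangeable by design.
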