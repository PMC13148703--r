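---
title: "Clique-centred biomarker screening: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clique-centred biomarker screening: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CliqueScreen)
```

## The procedure

`CliqueScreen` operationalises a simple structural hypothesis about
disease biomarkers: that validated biomarkers preferentially occupy
large, dense, evolutionarily conserved cliques of the protein–protein
interaction (PPI) network. The pipeline has five stages.

**Network assembly.** The query set is the top *N* genes of a
disease-scored gene list (scores on the 0–5 scale used by
gene–disease association databases), intersected with the gene
vocabulary of a confidence-scored edge table. Edges survive when
their combined confidence reaches the chosen cutoff; 0.4, 0.7 and 0.9
are the conventional medium/high/highest-confidence settings. Query
genes that map into the vocabulary but lose every edge at the cutoff
are kept as degree-0 nodes — they are part of the network's node
count and of enrichment denominators, but are excluded from every
centrality ranking, where they carry no signal. Gene identifiers are
matched exactly; alias resolution belongs to the upstream export, not
to this package. Disease-score ties at the query boundary break
lexicographically, so network construction is a pure function of its
inputs.

**Centrality ranking.** Twelve hub measures are computed from scratch
on the degree ≥ 1 subgraph, with unweighted hop distances and
unordered source–target pairs throughout. Per-measure conventions
that needed fixing:

* *Closeness* uses the harmonic form Σ 1/d(v,w) (unreachable genes
  contribute 0), so disconnected networks need no arbitrary component
  restriction; the classic component-restricted reciprocal-sum form is
  available via `metricParams(closenessForm = "classic")` for
  sensitivity checks.
* *MCC* sums (|C|−1)! over the maximal cliques containing a gene,
  enumerated with pivoting Bron–Kerbosch. Factorial terms are IEEE
  doubles, which represent k! exactly up to k = 23 — far beyond any
  clique size arising at the network sizes this package targets; the
  validity range is stated here rather than pulling in big-integer
  arithmetic.
* *EPC* retains each edge independently when a uniform draw is at
  least `epcThreshold` (default 0.5) and averages the size of each
  gene's surviving component over `epcIterations` (default 1000)
  replicates, divided by the node count. It is the one stochastic
  measure: it is seeded (`rngSeed`), bit-reproducible for a fixed
  seed, and its parameters are recorded in the table's metadata.
* *BottleNeck* grows one BFS shortest-path tree per root, scanning
  neighbours in lexicographic gene-id order with first discovery
  fixing the parent; a non-root gene is a bottleneck when its subtree
  (itself included) exceeds a quarter of the tree, strictly. The tie
  rule is a convention — shortest-path trees are not unique — and
  choosing a deterministic one means BottleNeck scores on graphs with
  many equal-length paths (e.g. cycles) depend on gene labels. That
  is the price of reproducibility, and the test suite asserts label
  symmetry only where the tie rule cannot break it.
* Ranks are competition ("1224") ranks: tied scores share the best
  rank, and the gene after a block of four co-leaders ranks fifth.

**Enrichment.** The top fraction *q* (default 0.05) of a ranking
takes the best ⌊q·n⌋ genes; when the boundary score is tied, every
tied gene joins the set and the enrichment rate is rescaled by
`nominal_k / extended_size`. This rescaling equals the expected rate
under random tie-breaking, which keeps low-resolution measures
(EcCentricity notoriously ties many genes) comparable to sharp ones;
both the rescaled and raw rates are reported, because averaging
conventions differ between the two whenever ties occur. Inclusion
denominators count every reference biomarker present in the network,
degree-0 genes included; the headline "share of biomarkers found"
quoted for an untied set is the raw ratio.

**Ranking-pattern comparison.** Biomarker ranks (full-network ranks,
not re-ranked within the biomarker subset) are correlated across
measures with Spearman's ρ (average-rank tie correction) and
clustered with classic Ward linkage (`hclust` method `"ward.D"`) on
the distance 1 − ρ, cutting the dendrogram at height 1 − 0.8 for the
conventional 0.8 correlation threshold. The Ward variant matters —
`ward.D` and `ward.D2` differ — so it is fixed and named here.

**Conservation, complex formation and the candidate screen.** A gene
earns 0.2 conservation points per panel species (five eukaryotes, so
the maximum is 1.0) in which it has a qualifying seed-ortholog pair:
inparalog score exactly 1.0 *and* seed score ≥ 0.95. The MCODE node
score k × density of the highest k-core of the closed neighbourhood
serves as the complex-formation proxy; only the vertex-weighting step
of MCODE is implemented — complex expansion, haircut and fluff
belong to cluster prediction, which this package does not do.
High-versus-low rank contrasts split the biomarkers at the median
rank into near-equal halves (rank ties break by gene id; an odd count
puts the extra gene in the high half) and use a two-sided Wilcoxon
rank-sum test: exact when the combined count is ≤ 20 and the values
are tie-free, the tie-corrected normal approximation otherwise.
Candidates are the non-biomarker members of the top set whose four
p-values — median-split log-rank for both survival endpoints
(patients exactly at the median go to the low-expression group), and
Dunn's z for the normal–tumor and tumor–metastatic contrasts — all
fall below 0.05. Dunn p-values are reported unadjusted, matching the
stated per-contrast criterion; a Bonferroni option exists. The
log-rank test comes from `survival::survdiff` (standard
hypergeometric variance at tied event times); Kruskal–Wallis from
`stats::kruskal.test`; Dunn's z is computed directly on the joint
ranks with the usual Σ(t³−t) tie correction, since no post-hoc
package is part of the dependency set.

## What the synthetic generator emulates

`syntheticSpec()` fixes the study conditions for everything
stochastic. The default spec generates 300 genes with two
vertex-disjoint planted K7 cliques over an Erdős–Rényi background
(edge probability 0.03), 16 reference biomarkers of which 75% occupy
clique positions, clique-edge confidences U(0.75, 1) against
background U(0.2, 0.9) (so cliques persist, though thinned, at the
0.9 cutoff while background edges wash out — reproducing the
qualitative degradation of biomarker detection at the
highest-confidence setting), a per-species qualifying-ortholog
probability of 0.3 boosted by +0.4 for clique members, exponential
survival with hazard ratio 2.5 for above-median expression of
hazard-linked genes (200 patients, baseline rate 0.02/month, uniform
censoring to 120 months), and expression-group means 0 / 1.5 / 3
(n = 50 per group) for the two designated true candidates.

Two sizing choices deserve explanation. First, the clique count ×
size (14) is deliberately below ⌊0.05 × 300⌋ = 15: a top-5% set can
then hold *every* clique member, which is the structural precondition
for recovering planted candidates through the screen; with more
clique slots than top-set places, recovery would be impossible by
construction rather than by statistical failure. Second, the effect
sizes (hazard ratio 2.5 at n = 200; 1.5σ group separation at n = 50)
are chosen so each individual filter has high power, because a
candidate must clear four filters jointly. Null specs (hazard ratio
1, zero shifts, zero boost) drive the same machinery to nominal 5%
type-I behaviour, which the test suite verifies at 1000 replicates
per test.

What the generator does *not* emulate: scale-free degree
distributions, overlapping cliques or protein complexes of
heterogeneous size, gene-identifier aliasing, the correlation
structure of real survival cohorts, or database-version effects.
Passing tests on this generator therefore demonstrate that the
algorithms are correct and that the pipeline recovers the structure
it assumes — not that any particular real network will show the same
enrichment levels.

## Numerical and degenerate-input choices

* Duplicate unordered edges collapse to the maximum confidence
  (conservative and idempotent); self-loops are dropped and counted.
* Density is an error below two nodes; node scores are an error for
  degree-0 genes; a constant-expression median split is an error
  (rather than a silent one-group log-rank).
* Unreachable pairs contribute 0 wherever a reciprocal is summed
  (closeness, EPC's component sizes count only the reachable) and are
  excluded from component-local quantities (radiality, eccentricity).
* All generators run under a locally seeded Mersenne-Twister stream
  and restore the caller's RNG state; derived seeds stay within the
  32-bit integer range.
* Problem sizes in the shipped tests: oracle equivalence uses a
  200-graph seeded family of ≤ 8-node connected graphs (exhaustive
  path/clique/core enumeration stays exact there), recovery uses 50
  seeds of the default 300-gene spec, and calibration uses 1000
  replicates per test — sizes chosen to make the statistical
  assertions sharp at interactive run times.

## Known limitations

* Centrality computation targets desk-scale networks (hundreds to a
  few thousand nodes); the shortest-path measures use dense n × n
  distance matrices and would need a compiled path for interactomes
  in the 10⁵-node range.
* MCC comparisons beyond clique size 23 would lose exactness (see
  above); no current input approaches that.
* The screen ingests survival and expression tables (or precomputed
  p-value flags); it does not query the public survival/expression
  databases those tables come from, so reproducing a published
  candidate list requires the corresponding per-gene exports.
* GO enrichment and semantic clustering of top sets, and any network
  visualisation, are out of scope.
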