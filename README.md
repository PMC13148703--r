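# CliqueScreen

Network-topology screening of disease biomarkers in protein–protein
interaction (PPI) networks.

Many clinically validated cancer biomarkers are not scattered randomly
through the interactome: they sit inside large, densely connected
cliques. `CliqueScreen` turns that observation into a reusable,
fully testable pipeline for people doing systems-biology biomarker
work in R. It

1. assembles confidence-filtered PPI networks from a disease-scored
   query gene list (DISEASES-style scores on a 0–5 scale) and a
   STRING-style edge table (combined confidence in [0,1], the usual
   0.4 / 0.7 / 0.9 medium/high/highest cutoffs);
2. ranks every connected gene with twelve hub-centrality measures —
   Betweenness, BottleNeck, Clustering Coefficient, Closeness, Degree,
   DMNC, EcCentricity, EPC, MCC, MNC, Radiality and Stress — written
   from scratch and verified against exhaustive oracles;
3. measures how strongly a reference biomarker panel is enriched in
   each measure's tie-aware top 5% across a query-size × confidence
   grid, and compares the measures' ranking patterns by Spearman
   correlation with Ward clustering;
4. relates rankings to evolutionary conservation (0.2 points per
   species with a qualifying seed-ortholog pair, five-species panel)
   and to MCODE-style node scores (complex-formation propensity);
5. screens the non-biomarker top-ranked genes through four filters —
   log-rank p for relapse-free and overall survival after a
   median-expression split, and Dunn p for normal-vs-tumor and
   tumor-vs-metastatic expression — and profiles the survivors'
   direct connectivity to the reference panel.

A seeded synthetic-data module generates all five input classes
(scored genes, edges, biomarker panel, ortholog tables,
survival/expression tables) with planted structure, so every stage of
the pipeline is exercised offline, with known ground truth.

## The core statistic

The headline measure is **maximal clique centrality (MCC)**. For a
gene *v* in an undirected network *G*,

```
MCC(v) = Σ_{C ∈ S(v)} (|C| − 1)!
```

where *S(v)* is the set of *maximal* cliques of *G* containing *v*
(enumerated exactly with pivoting Bron–Kerbosch). Membership in one
large clique dominates membership in many small ones; a gene whose
neighbourhood is edgeless scores exactly its degree. Network density
is `2m / n(n−1)`; the MCODE node score of *v* is `k × density(H)`
with *H* the highest *k*-core of *v*'s closed neighbourhood; top sets
use competition ("1224") ranking, with sets extended over boundary
score ties and enrichment rates rescaled by
`nominal_k / extended_size`.

## Worked example

```r
library(CliqueScreen)

spec <- syntheticSpec(rngSeed = 7)   # 300 genes, two planted K7 cliques
b    <- generateNetwork(spec)
net  <- buildNetwork(b$genes, topN = 300, b$edges, minConfidence = 0.4)
net
#> PPINetwork with 300 nodes and 983 edges
#>   confidence cutoff: 0.4
#>   degree-0 nodes: 1
#>   density: 0.02192

mcc <- mccCentrality(net)
inclusionRate(topFraction(mcc, 0.05), b$biomarkers, net)
#>   metric nominal_k extended_size tie_extended biomarkers_in_top
#> 1    MCC        14            14        FALSE                12
#>   biomarkers_in_network rate_percent rate_percent_raw
#> 1                    16           75               75

out <- screenPipeline(b, spec)       # four-filter candidate screen
out$candidates
#> [1] "G0194" "G0271"
b$truth$gene[b$truth$true_candidate] # the genes that were planted
#> [1] "G0194" "G0271"
```

The top-5% MCC set (14 of 299 ranked genes) captures 12 of the 16
reference biomarkers (75%), whereas betweenness captures 18.8% on the
same network — biomarkers were planted into cliques, and MCC is the
measure that sees cliques. The screen then recovers exactly the two
planted full-effect candidates, reporting their four p-values and
their connectivity to the biomarker panel (here 31–38% of the
reference set).

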