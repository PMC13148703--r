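Package: CliqueScreen
Title: Centrality-Based Biomarker Screening in Protein-Protein
    Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds confidence-filtered protein-protein interaction
    networks from disease-scored gene lists, ranks genes by twelve
    hub-centrality measures (including maximal clique centrality and the
    other cytoHubba-lineage metrics), quantifies enrichment of reference
    biomarkers in top-ranked sets over a query-size by edge-confidence
    grid, relates rankings to evolutionary conservation and MCODE-style
    complex-formation scores, and screens novel candidates through
    survival and differential-expression filters. Seeded generators for
    planted-clique networks, ortholog tables and survival/expression
    data make every stage testable without database downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
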