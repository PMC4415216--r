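Package: pathpanel
Title: Design and Validation of Pathway Reporter Gene Panels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to design targeted gene panels that report the activity
    of signaling and metabolic pathways. Harmonizes pathway-gene
    associations from multiple knowledge sources into a bipartite network,
    ranks genes by PageRank centrality on a transcriptional regulatory
    network, removes informationally redundant genes with a
    degree-preserving permutation test on shared pathway membership and
    with co-expression clustering, and assembles a reporter panel with a
    full per-gene audit trail. Includes an in-silico validation suite
    (functional enrichment against random baselines, disease-association
    density, cross-network centrality, interaction-role coverage with
    bootstrap confidence intervals), molecular-phenotyping analyses of
    targeted RNA count matrices (library-size normalization, rank-based
    single-sample pathway activity scores, peak-time ordering,
    subset-variance statistics, pathway regulation tests, polynomial trend
    tests), and a synthetic-data generator that plants hubs, redundant
    gene pairs, enriched annotation terms, disease-dense genes, and
    pathway activation profiles for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
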