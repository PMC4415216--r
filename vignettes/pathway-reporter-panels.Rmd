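---
title: "Designing and validating pathway reporter gene panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and validating pathway reporter gene panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathpanel)
```

## The problem

A cell's "molecular phenotype" is the activation pattern of its signaling
and metabolic pathways. Most of that pattern is visible in the expression of
a relatively small number of genes: the key upstream regulators of each
pathway and its characteristic transcriptional targets. A *pathway reporter
gene panel* is a few hundred such genes, chosen so that targeted RNA
quantification of the panel alone supports pathway-level inference across
many biological contexts. `pathpanel` implements the design of such panels
from knowledge inputs, their in-silico validation, and the downstream
phenotyping analyses, together with a synthetic-data generator that makes
the whole chain testable without any proprietary database.

## The design pipeline

### Knowledge harmonization

Pathway–gene associations from multiple sources are merged into one
bipartite graph (`harmonize()`): pathway nodes on one side, gene nodes on
the other, edges carrying a role (`regulator`, `target`, or `unspecified`)
and the set of contributing sources. Identical (pathway, gene, role) edges
merge their provenance; when sources disagree on the role, both role edges
are kept — the union view loses no information, and downstream steps use
membership only. Associations are deliberately context-free: no cell-type
or tissue fields are modeled, because the panel is meant to work across
contexts. Cross-source identifier mapping is a user-supplied two-column
table applied at read time; the package does not guess mappings.

### Centrality

Genes are ranked by PageRank on the transcriptional regulatory network
(`pagerank()`): power iteration of
\(x \leftarrow d\,P^{\top}x + d\,\mathbf{1}\,m_{\text{dangling}}/n +
(1-d)/n\), where \(P\) is the row-stochastic transition matrix of the
chosen orientation, dangling nodes spread their mass uniformly, and the
teleport vector is uniform. Defaults: damping \(d = 0.85\) (the standard
default of graph libraries), L1 tolerance \(10^{-10}\), at most 1000
iterations; non-convergence is an error carrying the last residual.
Multi-edges collapse before iteration — the walk is unweighted.

The phrase "the underlying unidirectional backbone" of a regulatory network
admits three readings, so all are implemented: `undirected` (default; each
directed edge collapses to one undirected edge), `directed` (source to
target), and `reversed` (target to source, which rewards upstream
regulators). The undirected skeleton is the default because it is the most
literal reading of an "underlying backbone" and is robust to annotation
direction errors; the choice is exposed as a parameter everywhere.

### Redundancy filtering

Two genes are informationally redundant when they report on essentially the
same pathways. `sicore_pairs()` tests, for every gene pair with at least
one shared pathway, whether the observed number of shared pathways exceeds
the expectation under a **degree-preserving null**: the bipartite graph is
rewired by checked edge swaps (two edges \((p_1,g_1), (p_2,g_2)\) become
\((p_1,g_2), (p_2,g_1)\) unless a duplicate would arise), which preserves
every pathway's and every gene's degree exactly. Each null replicate
restarts from the observed graph and performs ten attempted swaps per edge
— enough to decorrelate the replicate from the start state at the graph
sizes used here. The empirical p-value uses the add-one estimator
\(p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + N)\), so \(p\) is never
zero and the test is exact-level by construction. Following the original
procedure, significance is judged on the *raw* p at \(\alpha = 0.05\) —
no multiplicity adjustment — and from each significant pair the gene with
the lower PageRank centrality is removed.

The order of removals is not specified by the procedure's description, so
it is fixed for determinism: pairs are processed in ascending p (ties by
the lexicographic pair key), a pair is skipped when either member is
already gone, and a centrality tie removes the lexicographically later id.
The default \(N = 1000\) permutations is the package's test-scale setting;
the same code path accepts arbitrarily large \(N\) (the original procedure
used \(10^6\)).

Co-expression deduplication is separate: `coexpression_clusters()` forms
the connected components of the graph with edges where the reported
correlation is strictly greater than \(r_{\min} = 0.90\) (positive
correlations only — anti-correlated genes carry complementary, not
redundant, information), and `coexpression_dedup()` keeps only the
highest-centrality member of each cluster.

### Panel selection

`select_panel()` takes the top \(\lceil f \cdot n\rceil\) genes of the
non-redundant ranking (default fraction \(f = 0.2\)), truncates to
`max_size`, and then removes exclusion-list genes *without backfilling*,
mirroring the situation where a vendor rejects assay-unfriendly genes after
the panel is designed. Ceiling rounding is used because the fraction cut
should never be empty for small lists. Every candidate gene receives an
audit record with a terminal status, and `design_panel()` extends the audit
over the pruning stages so that each gene of the knowledge base appears
exactly once.

## In-silico validation

* `fisher_enrichment()` — per annotation term, the one-sided
  (over-representation) hypergeometric tail of the 2×2 table over a gene
  universe; the default universe is all genes with at least one annotation
  after evidence filtering (the analysis itself only fixes the evidence
  filter, so the universe is configurable). BH adjustment is applied across
  terms; `bh_adjust()` is implemented in the package and is cross-checked
  against the reference implementation in the tests.
* `disease_density_comparison()` — the panel's per-gene disease-association
  counts against the pooled counts of random same-size gene sets, compared
  by a two-sample KS test (asymptotic p; the samples here are hundreds of
  values, where the asymptotic approximation is accurate). The per-gene
  count distribution is compared — not set-level totals — and the
  mean-count ratio is reported alongside.
* `centrality_crosscheck()` — PageRank medians of panel versus background
  genes on a network *not* used for design.
* `interaction_coverage()` — the fraction of regulatory edges with a panel
  gene as source ("upstream"), as target ("downstream"), or as either
  ("involved"; fractions of edges, not of genes), with a percentile
  bootstrap baseline over random same-size gene sets.

## Molecular phenotyping

### Normalization

`log2_cpm()` computes
\(\log_2\!\big((c + 0.5)\,/\,(L + 1) \times 10^6\big)\) per gene and
sample, with library size \(L\) the column sum. The 0.5 pseudocount keeps
zeros finite; the \(+1\) library offset keeps the transform defined in
degenerate cases. Both offsets are configurable and vanish with coverage:
doubling all counts and the library size perturbs a gene with \(c \ge 50\)
by less than 0.01 log2 units.

### Pathway activity scores

Published single-sample scoring methods (GSVA and relatives) are external
algorithms with their own kernels; the package defines its own rank-based
score with a closed-form null, recorded in the `method` attribute as
`meanrank-z`. Per sample, all \(G\) profiled genes are ranked (average
ranks on ties); a pathway with \(m\) profiled members and mean member rank
\(\bar R\) scores

\[ z = \frac{\bar R - (G+1)/2}{\sqrt{(G+1)(G-m)/(12\,m)}}, \]

the exact standardization of a mean of \(m\) ranks drawn without
replacement from \(1..G\). The score is invariant under any strictly
monotone per-sample transform of expression, has null mean 0 and variance
1, and its sign reads directly as up- or down-regulation of the set.
Degenerate sets are contract errors: a set covering every profiled gene has
zero score variance (error); a set with no profiled member is skipped with
a warning. Scores are computed per sample; `average_by_condition()`
averages replicates for display, and `row_zscore()` standardizes each
pathway's profile (constant rows become zeros with a warning) for
between-pathway comparison. `peak_time_ordering()` sorts pathways by the
time point of maximal activity — a stable sort on the peak index, so
pathways peaking at the same time keep their input order — and classifies
them as `early` (peak at the first time point; the stem-cell-like profile),
`late` (peak at the last; cell-type-specific), or `transient` (interior
peak; "switch" pathways).

### Variance explained and regulation tests

Whether a reported variance fraction means a variance sum or a projection
is ambiguous, so `variance_explained_fraction()` implements both: `varsum`
(subset variance sum over total variance sum) and `projection` (fraction of
total centered variance explained by regressing all genes on the subset's
top principal components, \(\min(m, S-1)\) components); neither is claimed
to be the original computation.

`pathway_regulation_test()` asks, per pathway, whether its reporters are
over-represented among the differentially expressed panel genes: a
one-sided hypergeometric test on the 2×2 of reporter membership versus DE
status *within the panel* (the panel is the natural universe for a targeted
assay). `trend_test()` fits per gene an OLS polynomial of the covariate
(time or dose): degree 2 tests the linear and quadratic terms jointly by an
F-test; degree 1 uses the two-sided t-test on the slope. The direction is
the sign of the linear coefficient, and `lfc` is the fitted log2 change
between the extreme covariate values; `call_de()` applies the conventional
thresholds \(|\mathrm{lfc}| \ge 1\) and BH-adjusted \(p < 0.05\). A
zero-variance gene gets coefficient 0 and \(p = 1\) by convention. This
replaces moderated count-model machinery (edgeR/limma) by design: the OLS
contrast has a closed-form power oracle, which the tests exploit; its
p-values are exact under Gaussian noise and well calibrated on log2-cpm of
the simulated counts (verified by a KS uniformity check at 5,000 genes).

## The synthetic-data generator

`simulate_knowledge_base()` emits every input the pipeline reads — a
directed regulatory network, bipartite associations, a co-expression table,
annotation and disease tables — with planted truth. Each artifact uses its
own RNG stream derived from the master seed, so components regenerate
independently and byte-identically.

* **Network**: preferential attachment; background genes get \(1 +
  \mathrm{Pois}(1)\) out-edges, designated hubs \(15 + \mathrm{Pois}(5)\),
  so hub out-degree is at least five times the median. Hubs therefore
  dominate PageRank in every orientation.
* **Associations**: background genes carry exactly two pathway memberships
  (an unordered pathway pair, or "slot"). Slot collisions — two genes with
  fully identical membership — are genuine redundancies that the pipeline
  is expected to prune, and with ~900 background genes over
  \(\binom{30}{2} = 435\) slots a few hundred of them arise by pigeonhole.
  Hubs are pleiotropic: they join about a third of all pathways, drawn so
  that no two hubs share more than half of their memberships. This
  structure is deliberate: partial overlaps of that order sit in the bulk
  of the degree-preserving null and are never flagged, whereas identical
  memberships are always flagged. A *uniformly random* membership graph
  would not behave this way — a calibrated test at raw \(\alpha = 0.05\)
  flags about 5% of all co-membership pairs, which over the quadratically
  many pairs of a 1,000-gene knowledge base prunes most of the gene list
  and no planted structure survives. The generator therefore plants
  redundancy explicitly (clone pairs with identical membership of size 6)
  and otherwise keeps memberships either minimal (background) or
  bounded-overlap (hubs). Real knowledge bases have diffuse intermediate
  overlap; passing tests on this generator demonstrates correct mechanics
  and calibration, not performance on that intermediate regime.
* **Annotations**: background terms at \(\mathrm{Pois}(2)\) per gene with
  mixed evidence codes; designated enriched terms annotate a fixed fraction
  of the hubs with experimental codes only, so evidence filtering plus
  enrichment testing has a planted signal.
* **Diseases**: per-gene association counts \(\mathrm{Pois}(\lambda)\) with
  \(\lambda\) three times higher for hubs — the planted density excess.
* **Co-expression**: planted clusters with within-cluster correlations in
  (0.92, 0.99) over a background of weak pairs.
* **Counts** (`simulate_expression()`): negative-binomial with log-normal
  baseline means, variance \(\mu + \phi\mu^2\) (default dispersion
  \(\phi = 0.1\), the order observed for biological replicates of bulk
  RNA counts), uniform library sizes, and planted per-condition log2
  fold-changes added to the activated pathways' member genes before
  per-sample renormalization — so activation also produces the
  compositional shift real cpm data shows. `triphasic_activation()` builds
  the early / transient / late triangular profiles used in the temporal
  simulations (peak effect 1.5 log2 units, the scale of clear pathway
  switches in differentiation time courses).

## Problem sizes and numerical choices

The test suite runs the full chain at the default knowledge-base scale
(1,000 genes, 50 hubs, 30 pathways, \(N = 1000\) permutations), temporal
phenotyping at 30 pathways × 15 genes × 4 time points × 3 replicates over
20 simulation replicates, and drug-response phenotyping at the panel shape
of 150 pathways × 6 reporters (900 genes) over 50 replicates — sizes chosen
so that every stochastic check has enough replication to be stable at its
asserted threshold while the whole suite stays fast. PageRank agreement
with a dense power-iteration oracle is checked to \(10^{-8}\) on 100 random
graphs; score sums are required to be within \(10^{-9}\) of one; Fisher
p-values match brute-force enumeration to \(10^{-12}\) on universes up to
30 genes.

## Known limitations

* The activity score is a defined rank statistic, not a reimplementation of
  GSVA; scores are comparable within this package only.
* The trend test assumes approximately Gaussian noise on the log2-cpm
  scale; for very low counts a count-model test would be preferable.
* The permutation null assumes the bipartite graph's degree sequence is the
  right conditioning; knowledge bases with strong pathway-size artifacts
  may need a stratified null.
* The synthetic generator's membership structure is intentionally
  polarized (see above); it validates mechanics and calibration, not
  performance on diffusely overlapping real knowledge bases.
* Text mining, primer design, and live database access are out of scope;
  all inputs are files.
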