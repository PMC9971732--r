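---
title: "Methods: network-pharmacology inference with netpharm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-pharmacology inference with netpharm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharm)
```

## The analysis this package implements

Network pharmacology asks how a drug class may act on a disease when no
single target explains the effect: drug targets and disease genes are
mapped onto a protein–protein interaction (PPI) network, and the structure
of that network — its hubs, its dense modules, its enriched pathways — is
read as a mechanistic hypothesis. netpharm implements the complete
inference chain for the common study design of a small set of drugs (e.g.
GLP-1 receptor agonists) against a disease pair (e.g. type 2 diabetes with
myocardial infarction):

1. **Target aggregation.** Per-source target lists are normalized
   (uppercased, trimmed, optionally alias-mapped) and unioned per entity,
   with per-gene provenance. Unmapped tokens are kept, not dropped, so set
   sizes stay conservative and auditable.
2. **Intersection.** A Venn decomposition of the drug-target union against
   the disease sets yields the intersection targets.
3. **Association expansion.** The intersection set is expanded with the
   top-*k* most associated genes from a weighted functional-association
   network (default *k* = 20).
4. **PPI filtering.** A STRING-style weighted edge list is filtered at
   confidence ≥ 0.7 and disconnected nodes are removed.
5. **Consensus hubs.** Four centralities — degree, maximum neighborhood
   component (MNC), maximal clique centrality (MCC) and edge percolated
   component (EPC) — are computed on the filtered network; a gene is a core
   target iff all four of its values are strictly above the per-algorithm
   means.
6. **Module mining.** MCODE vertex weighting and greedy complex growth
   partition the network into dense modules, each reported with its growth
   seed (its highest-weight vertex) and density × size score.
7. **Enrichment.** Over-representation analysis (one-sided hypergeometric,
   Benjamini–Hochberg q-values, odds ratios) ranks library terms for the
   related set (by q) and per module (by odds ratio); transcription-factor
   regulons are ranked by a permutation normalized enrichment score (NES).
8. **Tripartite network.** Drug, disease and target nodes are joined by
   membership edges; the all-drug common-target set is reported.

## Statistics and their definitions

**Expansion score.** For a non-seed gene *g* with seed neighbors *s*,
`score(g) = Σ_s w(g, s) / sqrt(deg(g))`, where `deg(g)` is *g*'s full
degree in the association network. This is a deliberate, deterministic
substitute for service-based association tools (whose label-propagation
internals are neither public in exported data nor reproducible offline):
only direct seed adjacency counts, promiscuous genes are discounted by
`sqrt(deg)`, ties break lexicographically, and zero-score genes are never
returned even when fewer than *k* candidates score positively.

**MNC.** The size of the largest connected component of the subgraph
induced by the open neighborhood N(v); 0 for isolated nodes.

**MCC.** `MCC(v) = Σ_{C ∋ v} (|C| − 1)!` over maximal cliques *C*,
enumerated by Bron–Kerbosch (igraph's pivoting implementation) with a
configurable clique-count cap (default 10^6) that aborts with a typed
error on pathological graphs. Factorial sums are computed in doubles,
which is exact for maximal cliques of up to 19 vertices (18! < 2^53); a
larger clique triggers a warning. PPI networks at this scale (tens of
nodes, cliques of size ≤ ~8) are far below the bound.

**EPC.** The expected size of v's connected component when each edge is
independently retained with probability `retention_p` (default 0.5),
estimated over `replicates` Monte-Carlo percolations (default 1000) with a
recorded seed. At `retention_p = 1` the estimate is exact (the component
size); at 0 it is 1. The estimator's standard error scales as
`sd/sqrt(replicates)`; the test suite checks it against exact `2^m`
edge-subset enumeration on small graphs.

**Consensus rule.** Strictly greater than the mean, on all four
algorithms simultaneously, with means taken over all nodes of the analyzed
(post-filter, post-isolate-drop) graph. Ties at the mean fail: on a
vertex-transitive graph (e.g. the 5-cycle) every value equals its column
mean and the hub set is empty. Edge weights are ignored by all four
centralities — the confidence filter is the only place weights act,
mirroring how these statistics are conventionally applied to filtered
networks.

**MCODE.** Vertex weight = `k × density` of the highest k-core of the
closed neighborhood N[v]; vertices with degree < `degree_cutoff` (default
2) weigh 0 and never seed or join complexes. Growth from the
highest-weight unassigned seed admits unassigned neighbors whose weight is
*strictly* greater than `w(seed) × (1 − node_score_cutoff)` (default
cutoff 0.2). The strict inequality is load-bearing: two planted cliques of
sizes 6 and 5 joined by a single bridge have boundary weights of exactly
4 = 5 × 0.8, so a non-strict rule would merge them; the strict rule, which
follows the algorithm's reference description, keeps them separate.
Post-processing discards complexes lacking a 2-core, then (haircut)
iteratively removes degree-1 members; the score `density × size` is
computed after post-processing. Ranking is by score, then size, then seed
name; fluff (overlapping complexes) is intentionally unsupported and
rejected with a typed error.

**ORA.** For overlap k of an n-gene query (restricted to the universe)
with a K-gene term in an N-gene universe,
`p = Σ_{i≥k} C(K,i) C(N−K, n−i) / C(N,n)`, `q` = Benjamini–Hochberg over
all terms of the library, odds ratio `k·d/((K−k)(n−k))` with `+Inf` when a
denominator cell is zero and k > 0, and 0 when k = 0. Zero-overlap rows
are retained at p = 1 so the BH family size equals the library size. The
universe defaults to the union of term genes; a larger fixed background
(e.g. 20000 protein-coding genes) can be supplied as `background_n`.
Because web enrichment services use internal, version-dependent
backgrounds, odds-ratio magnitudes from such services are not comparable
across backgrounds and are not targets for this implementation.

**Permutation NES.** Motif/ChIP-track-based regulon scoring cannot be
computed offline, so TF ranking uses an explicitly labeled substitute with
the same ranking semantics: the observed regulon overlap k is standardized
against the overlap distribution of `n_perm` (default 1000, minimum 100)
random query-sized gene sets drawn uniformly from the universe,
`NES = (k − mean_null)/sd_null` (0 when the null is degenerate), ranked by
NES, then target count, then name.

## The synthetic-data generator

The study design this package addresses draws its inputs from proprietary
web databases, so the generator produces structurally equivalent inputs
with recorded ground truth (`verify_fixture()` re-checks every claim
against the artifact):

* **Target sets** are built constructively: overlap-region counts are
  specification, not expectation, so a Venn over the generated sets
  reproduces them exactly; nesting constraints (every gene of an inner set
  belongs to its outer set, as with a myocardial-infarction set contained
  in a diabetes set) are applied by signature closure.
* **PPI graphs** plant fully wired cliques (weights U(0.7, 1), so the 0.7
  filter never removes a planted edge) and hub nodes attached to every
  member of three cliques, over an Erdős–Rényi background (weights
  U(0.4, 1), so the filter removes a seed-dependent background fraction).
  Two structural constraints keep the recorded truth exact under the
  downstream algorithms: background–background edges form a forest (any
  background cycle is a 2-core, i.e. a spurious MCODE module), and planted
  hubs are never adjacent to each other (a hub–hub edge merges their
  cliques into larger maximal cliques, inflating every clique member's MCC
  past the hubs'). Designated low-confidence nodes carry only
  sub-threshold edges and drop out at the filter, emulating nodes hidden
  as disconnected. One sizing condition matters when composing fixtures:
  with *h* hubs each attached to all members of equal-size cliques, a
  clique member's MCC is *h* · s! (one maximal clique per hub) while a
  hub's is only c · s! over its *c* cliques, so hubs clear the MCC *mean*
  only by background dilution — roughly N > 7·h analyzed nodes are needed.
  Fixture hub counts are therefore kept small relative to the network
  (e.g. 3 hubs in the ~40-node demo network, 5 hubs in the ~50-node
  recovery benchmarks).
* **Association networks** connect each planted associate to at least 3
  seeds at weights U(0.6, 1) and background genes to at most one seed at
  U(0.1, 0.5), so the expansion score separates the classes by
  construction.
* **Libraries** mix uniform random terms with planted terms included
  verbatim.

The bundled `demo_config()` instantiates the full study shape at desk
scale: three drugs sized 77/77/56 with a 12-gene all-drug core, nested
disease sets (120 ⊆ 300) arranged so the drug-union/disease intersection
is exactly 31, an association network with 20 planted associates (related
set of 51), and a PPI layer over the 51 related genes with planted cliques
of sizes 6/5/4, 3 hubs and 5 sub-threshold nodes. Set sizes and counts
(77/77/56, 31, 20, 51, 12, confidence 0.7, k = 20, top-5/top-3) are the
study conditions; where a value was unstated (universe size 600,
background edge probability 0.05, library sizes) we fixed a single
realistic choice.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: scale-free degree distributions and hub-length
correlations of real interactomes, correlated evidence channels behind
STRING confidence scores, overlapping protein complexes, curation biases
of target databases, and the hierarchical redundancy of real ontologies.
Recovery rates on planted structure are upper bounds on real-data
behavior, not estimates of it.

## Numerical and design choices

* The confidence threshold comparison is inclusive (≥ 0.7), matching the
  convention of STRING's "high confidence 0.700" preset.
* Score scales auto-detect: a STRING-dialect 0–1000 `combined_score`
  divides by 1000 iff any score exceeds 1.
* Duplicate/reversed edge rows collapse keeping the maximum weight;
  self-loops are dropped.
* All randomness (EPC, NES permutations, generators) flows through seeded,
  state-preserving RNG scopes; the pipeline derives fixed per-stage
  sub-seeds from one master seed, so adding a stage never shifts another
  stage's stream, and reruns of the same config + seed are byte-identical.
* Degenerate inputs have defined behavior rather than errors where a
  convention exists (empty gene lists are empty sets; k = 0 overlaps give
  p = 1 and odds ratio 0; an edgeless graph has EPC 1 everywhere) and
  typed errors where none does (empty graph for hub analysis, no seed in
  the association network, unsatisfiable set specifications).
* Venn decomposition supports 2–6 sets; beyond 6 the 2^k − 1 region
  signatures stop being interpretable and the call is rejected.

## Problem sizes in the test suite

The suite checks the centralities against exhaustive oracles (bitmask
clique enumeration, 2^m percolation enumeration) on 200 random graphs of
4–12 nodes; hub recovery on 40 seeded planted-hub fixtures (~53 nodes);
MCODE recovery on 20 seeded three-clique fixtures; the hypergeometric tail
against direct summation over the full (N ≤ 60, n, K, k) domain and
against exhaustive subset counting at N ≤ 9; BH against the step-up
definition; and null-library calibration over 200 simulated queries.
These sizes make every oracle exact while keeping the whole suite fast;
they are structural choices, not statements about the limits of the
implementation.

## Known limitations

* The association expansion and the permutation NES are substitutes with
  the same ranking semantics as the web tools they replace, not
  re-implementations of those tools; absolute scores are not comparable.
* MCC loses integer exactness beyond 19-vertex maximal cliques.
* Fluff (overlapping MCODE complexes) is not implemented.
* Odds ratios depend strongly on the chosen background universe; compare
  them only within one library and one background.
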