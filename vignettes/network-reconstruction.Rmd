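---
title: "Seed-anchored gene-metabolite network reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-anchored gene-metabolite network reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabonet)
```

## The model

`metabonet` reconstructs a directed bipartite-with-extras network around a
small set of *seed genes*. Nodes are metabolites, metabolic genes
(enzymes, i.e. genes attached to at least one reaction) and signaling
genes (genes that appear only in gene–gene relations). Edges encode
reaction participation — substrate → enzyme and enzyme → product, with
mirrored edges for reversible reactions — plus enzyme-independent
gene → gene regulatory links. This is deliberately not a hypergraph and
carries no stoichiometry: the questions the network answers are about
*adjacency and reachability* (what lies within a few biochemical steps of
the seeds), not flux.

Pathways are merged by exact namespaced identifier (`cpd:...` compound
ids, `hsa:`/`gsy:`-style gene ids kept verbatim), so a compound shared
between pathways — the carbamoyl phosphate linking the urea cycle to
de novo pyrimidine biosynthesis, say — becomes a single node through
which the pathways connect. Merging is a set union: it is commutative in
pathway order, and duplicated pathways change only the edge provenance
lists, never the node or edge sets.

Several mapping choices are worth making explicit:

* A KGML entry naming several genes is parsed losslessly as one entry and
  expanded to one node per gene at network-build time; group entries are
  expanded to their members and are not nodes themselves.
* `ECrel` (enzyme–enzyme via a shared compound) relations produce no
  edges: the coupling is already present through the reaction edges, and
  adding them would double-count adjacency.
* `PCrel` (protein–compound) relations are typed `gene_to_product`, the
  closest available semantic category; provenance records the relation.
* A gene found in both reactions and relations is classified metabolic:
  the reaction role dominates in a metabolite-centric network and the
  partition must be deterministic.
* Self-loop edges are dropped with a warning; they carry no distance or
  pruning information.
* Reversible reactions yield mirrored edge pairs. Under the default
  undirected distance this choice is invisible; it matters only for the
  directed distance modes.

## The filtering cascade and its parameters

| parameter | default | meaning |
|---|---|---|
| `max_steps` | 3 steps (edges) | distance budget from the nearest seed |
| `distance_mode` | `undirected` | how "steps away" is measured |
| `expression_threshold` | 0 | expressed means value strictly above this |
| `prognosis_alpha` | 0.001 | label a gene's prognosis iff log-rank p < alpha (strict) |
| `min_metabolite_neighbors` | 2 | survival threshold for metabolic genes |
| `prune_to_fixpoint` | `TRUE` | iterate the structural rules until stable |

The 3-step budget reflects a practical reading radius: fewer steps
oversimplify a merged multi-pathway network, more make it unreadably
entangled. Distance is undirected by default because "steps away from a
seed" is a symmetric notion and a directed reading would hide everything
upstream of the seeds; the three directed modes are kept for sensitivity
analysis. The distance filter applies to *all* non-seed nodes, genes
included — a gene kept while its metabolites are dropped would be an
orphaned enzyme. Distances exported in the node table are the pre-filter
values; pruning does not trigger recomputation, so one "calculate, then
filter" pass stays reproducible.

The expression filter removes gene nodes with no record in the target
tissue as well as those at or below the threshold: absence of evidence is
reported (in the join report) but an unrecorded gene cannot be claimed
expressed. Metabolites are never expression-filtered.

Structural pruning applies two rules: (a) remove nodes with no undirected
path to any seed, and (b) remove metabolic genes with fewer than two
distinct metabolite neighbours, since a gene connected to a single
metabolite cannot represent a complete substrate-product reaction.
Signaling genes are exempt from (b) — they make no reaction claim — but
not from (a). Because each rule's removals can create violations of the
other (removing an under-connected enzyme can strand its private
metabolite), the default iterates both to a fixed point, which also makes
the result independent of rule ordering and node iteration order; a
single-pass mode emulates a one-shot manual filter.

Two edge cases are defined explicitly. A *seed* metabolic gene falling
under rule (b) is an error, not a silent removal: a network whose anchor
enzyme lacks a representable reaction indicates broken input, and seeds
must never be pruned. But when no metabolite nodes remain at all — e.g.
after a 0-step distance filter leaves only the seeds — rule (b) is
vacuous: with no metabolites there is no reaction left to represent, and
the seeds-only network is the legitimate result.

## Annotation semantics

The three layers (expression, survival prognosis, urine detectability)
join by exact identifier, optionally through a caller-supplied alias
table; there is no fuzzy matching, because a silent mis-join is worse
than a reported miss. Every call returns a join report with
matched/unmatched counts summing to the input row count. Missing
annotations stay *absent* (`NA`, exported as empty fields), never false
or zero: absence of evidence is not negative evidence. The prognosis
label is the record's direction exactly when p < alpha with strict
inequality, so a boundary p equal to alpha yields `"none"`. Annotation
never changes network topology.

## The synthetic-data module

`make_toy_fixture()` returns a fixed pair of pathways with fictional
identifiers: a four-reaction urea-cycle analog (carbamoyl-phosphate +
ornithine → citrulline → argininosuccinate → arginine → ornithine + urea,
catalysed by OTC/ASS/lyase/arginase analogs) and a linear pyrimidine
chain (glutamine analog → carbamoyl-phosphate → carbamoyl-aspartate →
dihydroorotate → orotate) catalysed by carbamoyl-phosphate-synthetase and
CAD analogs plus one relation-only signaling gene. Both seed genes sit in
the chain pathway, with the synthetase analog producing the shared
connector compound the cycle consumes — the same linkage through
carbamoyl phosphate that couples the real pathways. The accompanying
manifest carries hand-enumerated counts for every pipeline stage, all
node distances, and the final node list; the test suite re-derives all of
it with an independent brute-force shortest-path oracle and a
definition-level pruning fixpoint, so the fixture is never trusted on its
own authority.

`random_pathways()` and `random_annotations()` generate seeded random
inputs: reactions with 1–2 substrates/products and one catalysing gene
drawn from shared pools (so cross-pathway compound sharing is exercised),
`PPrel` relations between distinct genes, and annotation tables with
exact controlled fractions (`floor(frac * n)`) of expressed, prognostic
and urine-detectable entries. Generators use a named seed and restore the
global RNG state. What the synthetic inputs do *not* emulate: real KEGG
pathway sizes (hundreds of entries), multi-gene enzyme families with
aliasing, patient-level survival data, or identifier noise between
databases. Passing tests therefore demonstrate the correctness of the
graph algebra, the cascade semantics and the exports — not robustness to
real-database identifier drift, which exact-id joining reports rather
than resolves.

## Numerical and engineering choices

* Distances are unweighted edge counts computed with igraph's
  shortest-path engine; the test oracle is an independent Floyd–Warshall
  implementation compared across all four modes on hundreds of seeded
  random networks (kept at or below 30 nodes so the cubic oracle stays
  instant).
* Unreachable nodes carry `NA` as sentinel, removed by any distance
  filter.
* All writers emit UTF-8, Unix newlines, tab delimiters, canonically
  sorted rows (nodes by kind then id; edges by source, target, type), so
  identical networks produce byte-identical files regardless of
  in-memory ordering — the property the golden-file tests assert.
* Absent attributes export as empty strings, not `"NA"`, which Cytoscape
  treats correctly as missing.
* GraphML is written with typed attribute keys and read back into an
  identical network (nodes, edges, kinds, attributes, seeds) — a
  round-trip contract the suite checks on annotated and bare networks.

Test and acceptance problem sizes (the package's own choice of scale):
200 random networks for the distance-oracle comparison, 50 for filter
monotonicity, 100 for the pruning postcondition, each well under 30
nodes; the end-to-end golden check runs on the 19-node toy fixture.

## Known limitations

* No stoichiometry, flux or kinetics; reactions with multiple substrates
  and products are flattened to pairwise edges.
* Identifier joining is exact; cross-database symbol drift must be
  handled by the caller through the alias table.
* Distance is topological, not biochemical: one promiscuous cofactor
  compound can shorten many paths. Curating pathway inputs (or filtering
  hub compounds upstream) remains the caller's responsibility.
* The prognosis layer consumes precomputed log-rank p-values; survival
  analysis itself is out of scope.
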