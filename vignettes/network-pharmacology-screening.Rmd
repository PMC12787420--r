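---
title: "Centrality-based hub screening for multi-herb formulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Centrality-based hub screening for multi-herb formulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(netpharm)
```

## The problem

Multi-herb formulations contain dozens to hundreds of phytochemicals, each
with many predicted protein targets, so their pharmacology is intrinsically
multi-target. Network pharmacology addresses this by chaining together a
small number of well-defined steps: curate the formulation's compounds and
their predicted targets, intersect those targets with a disease gene set,
build a protein–protein interaction (PPI) network over the shared genes,
condense that network to a handful of topological hub ("core") genes, test
the core for pathway enrichment, and assemble everything into a
drug–herb–compound–target–pathway (D-H-C-T-P) summary network.

`netpharm` implements that chain as plain R functions over plain-text
formats (TSV tables, gene lists, STRING-style edge lists, GMT libraries),
with seeded generators standing in for the live databases (compound
catalogues, disease-gene portals, STRING, enrichment services) that such
studies normally query. Every stage is therefore reproducible and testable
offline.

## Ingestion and overlap

`read_compound_table()` applies the only curation rules these tables need:
exact (herb, CID) duplicates are dropped, while the same compound listed
under two herbs is kept twice — shared constituents such as glycyrrhizin
are genuinely part of both herbs, and per-herb compound counts are reported
that way. `read_target_map()` uppercases and deduplicates gene symbols; no
alias resolution is attempted (a documented limitation — symbol aliasing
policies differ between databases, and guessing one silently changes
counts). `drop_targetless()` removes compounds with no annotated target,
and `union_targets()` forms the formulation's predicted target set.

```{r}
compounds <- read_compound_table(
  system.file("extdata", "mecasin_compounds.tsv", package = "netpharm"))
nrow(compounds)
table(compounds$herb)
```

`overlap_summary()` intersects the predicted targets with a disease gene
list and, when a universe size is given, attaches an exact hypergeometric
upper-tail p-value. The universe is deliberately an explicit argument: the
portals these gene lists come from state no common background, and the
p-value is meaningless without one. When the downstream PPI network is
available its gene set is a defensible default universe.

## Centralities

`build_graph()` turns a scored edge list into a simple undirected igraph
object: edges below `min_score` are dropped (default 0.7, the customary
"high confidence" STRING cutoff), self-loops removed, duplicate pairs
collapsed to their maximum score. Scores on the 0–1000 integer scale are
auto-detected on read.

Three centralities drive the screening, all computed on **unweighted**
(hop-count) shortest paths — confidence scores filter edges but are never
treated as distances. This matches how topology screens are run in
practice and makes the reference values exact rationals:

* degree `dc`: the neighbour count, kept as an unnormalized integer;
* betweenness `bc`: Brandes' $\sum_{s \ne v \ne t} \sigma_{st}(v)/\sigma_{st}$,
  normalized by $(n-1)(n-2)/2$;
* closeness `cc`: component-restricted, $(n_c - 1)/\sum_u d(v, u)$ within a
  component of size $n_c$; isolated nodes score 0, and no cross-component
  scaling is applied (the networks of interest are connected; the
  convention only matters for degenerate inputs).

A useful identity anchors these conventions: in any graph containing a
universal node, every non-neighbour of a node $v$ sits at distance exactly
2, so $cc(v) = (n-1)/(dc(v) + 2(n-1-dc(v)))$. The 40-node generator
`gen_table2_network()` plants a universal hub and fixed labeled degrees
(39, 36, 36, 36, 35, 35), so the labeled closeness values are the exact
rationals $39/39$, $39/42$ and $39/43$ for every seed:

```{r}
cc <- closeness_centrality(gen_table2_network(seed = 1))
round(cc[c("IL6", "AKT1", "TNF")], 9)
```

## Iterative mean-threshold screening

`screening_round()` computes the three centralities, takes each metric's
arithmetic mean over the current nodes as its threshold, and retains the
nodes **strictly above all three** means. `iterative_screen()` repeats this
on the induced subgraph of the retained nodes — thresholds are recomputed
each round, which is what makes successive degree thresholds equal $2E/N$
of each round's own graph (handshake lemma), an identity the audit trail
exposes and the tests assert. Isolated nodes created by the induction are
carried forward; their zero closeness removes them in the following round,
so no node is ever dropped silently.

Stopping (`policy`) is by convergence (a round retains everything — or
nothing, in which case that round's input set is the core), a fixed round
count, or a target size. Strict inequalities guarantee termination: a
perfectly regular graph (e.g. the final clique) retains nothing, so the
clique itself is reported as the core.

### The retention rule, and why it is configurable

The conjunction rule ("above the mean on *all* metrics") is the standard
hub definition in centrality-screening workflows, and on heavy-tailed
PPI-like graphs it retains roughly 20% of nodes per round, which is the
regime published screens operate in. It has, however, a sharp failure mode
near symmetric cores: in a graph that is a clique plus a few weakly
attached stragglers, clique members that happen to lack a straggler link
sit *exactly at* the degree mean and at betweenness exactly 0 (below any
positive mean), so the conjunction can prune parts of a genuine clique
core before the stragglers are gone. `rule = "any"` (retain nodes above
the mean on at least one metric) is the documented sensitivity variant: it
preserves clique cores essentially always, at the price of much slower
condensation (roughly 40% retention per round on the same graphs). The
default remains `"all"` because it is the rule the screening literature
describes; the planted-core recovery experiment in the test suite measures
both behaviours rather than hiding the difference.

## Synthetic data: what it emulates and what it does not

`gen_planted_core_network()` draws the topology in which mean-threshold
screening has a ground truth: a `core_size`-clique whose members each
attach to a fraction `core_attach_frac` of the periphery, over an
Erdős–Rényi background with density `bg_edge_prob`, repaired to
connectivity by wiring any detached component to a random core node.
The defaults used throughout the tests (n = 300, core 6, attachment 0.4,
background 0.01) give core degrees near 120 against periphery degrees near
5 — an unambiguous planted signal. Edge scores mimic a high-confidence
STRING export (planted edges 0.90–1.0, background 0.70–0.90).

`gen_compound_target_data()` draws the tabular study inputs. Its defaults
are the study conditions the pipeline was built around: nine herbs
contributing 6, 20, 5, 17, 34, 83, 17, 5 and 5 compounds (192 in total),
an 8886-gene disease set, and a 20000-gene universe — the scale of the
human protein-coding genome, since the source portals state no background.
`overlap_enrichment` defaults to 1 (the null model: disease genes drawn
uniformly, making the target/disease overlap exactly hypergeometric, which
is what the calibration tests require); values above 1 up-weight predicted
targets in the disease draw, planting genuine disease relevance.

`gen_annotation_library()` draws GMT libraries with optional planted
enrichment: planted terms over-sample a query set with weight
`enrichment_factor`. At factor 1 every term is a null draw, giving the
type-I calibration fixture; at factor ≥ 5 planted terms should (and in
tests do) dominate the top ranks.

None of these generators attempt realistic degree distributions,
annotation hierarchies, or correlated gene sets. Passing tests therefore
demonstrate algorithmic correctness and statistical calibration on the
assumed structures, not fidelity to any real interactome.

All generators are pure functions of their spec and seed (RNG state is
scoped with `withr::with_seed`, leaving the session's RNG untouched), so
repeated calls are byte-identical through the writers.

## Enrichment

`fisher_enrich()` is a deliberately plain over-representation analysis:
one-sided hypergeometric (Fisher's exact) p-values against the library's
universe (default: union of term genes, overridable), Benjamini–Hochberg
adjustment via `bh_adjust()`, and `top_k()` ranking by raw p with ties
broken by larger overlap then term id. Service-specific composite scores
(such as rank-deviation corrected combined scores) are intentionally not
reimplemented — they depend on the service's precomputed background
ensembles and are not reproducible offline. The exact test is discrete and
therefore conservative: under the null the rejection rate at 0.05 sits at
or slightly below 0.05, which the calibration tests account for.

## The D-H-C-T-P network

`assemble_dhctp()` integrates the stages into a five-layer multipartite
network (drug → herbs → compounds → core targets → pathways). Edges may
only connect adjacent layers — the constructor enforces this, and node ids
are layer-prefixed so a compound and a gene can share a display name.
Compounds that hit no core gene are omitted along with their herb edges,
keeping the network free of dead branches (configurable only by passing a
larger core). `layer_degree()` counts a node's links toward the next
layer, the quantity these studies report ("compound X hits 5 core genes",
"gene Y sits in 6 pathways"). Exports: SIF, GraphML and a node/edge TSV
pair, all losslessly re-importable.

## Numerical and testing choices

* Centralities are validated against brute-force oracles (Floyd–Warshall
  distances plus walk-count shortest-path enumeration, written without
  igraph) on 100 random graphs with up to 8 nodes, at tolerance 1e-12.
* Hypergeometric tails are validated against exhaustive subset enumeration
  for every configuration with a universe of 12 or fewer genes.
* Threshold displays round degree means to 5 decimals and
  betweenness/closeness means to 6; comparisons always use full precision
  (rounding is presentation only).
* Problem sizes in the test suite (planted networks of 150–300 nodes,
  enrichment universes of 1000–2000 genes, 100–200 seed replicates) are
  chosen so the full suite and the acceptance script each run in well
  under a minute on one CPU while keeping Monte-Carlo standard errors
  small relative to the asserted tolerances.

## Known limitations

* Gene symbols are matched textually after case-folding; no alias or
  orthology resolution.
* The screening's behaviour is characterised only on planted-core
  synthetics; on real PPI networks the "correct" core is not identifiable,
  and the audit trail (`thresholds_report()`) is the only ground truth.
* Pathway membership in the D-H-C-T-P network is an input table, not a
  live pathway-database lookup.
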