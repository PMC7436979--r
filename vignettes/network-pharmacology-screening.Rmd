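---
title: "Topological screening of multi-component drug targets: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological screening of multi-component drug targets: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharm)
```

## The problem

Multi-component preparations — herbal formulas in particular — act through
many low-affinity interactions rather than one high-affinity target. The
standard network-pharmacology screen asks: given the predicted protein
targets of a formula's active compounds and the genes associated with a
disease, which proteins sit at the topological core of the shared
interaction neighborhood, and which biological pathways do they implicate?
netpharm implements that screen as a reproducible, file-driven pipeline:

1. integrate compound→target and disease-target tables (official gene
   symbols, uppercased, deduplicated, with per-source provenance);
2. intersect them to obtain the *common targets*;
3. induce a protein–protein interaction (PPI) network on the union of both
   target sets, keeping edges with combined confidence strictly above a
   threshold (default 0.4) and discarding interaction-free nodes — the
   CT-OT network;
4. extract the *hub network*: the common targets plus their first
   neighbors, as a full induced subgraph, isolates removed;
5. screen *key targets* by node topology: degree strictly above twice the
   median degree, betweenness and closeness centralities strictly above
   their medians, all medians taken over the network being screened;
6. test the key targets for gene-set over-representation, select the top
   pathways, and map them onto a disease-associated pathway list;
7. assemble compound–target and compound–target–pathway networks, and
   normalize docking scores by each receptor's original-ligand score.

## Model and conventions

**Centralities.** For an unweighted simple graph with $N$ nodes,
betweenness is Brandes-accumulated and normalized by the number of
unordered pairs excluding the node,

$$C_B(v) = \frac{2}{(N-1)(N-2)} \sum_{s \ne v \ne t} \frac{\sigma_{st}(v)}{\sigma_{st}},$$

so $C_B \in [0,1]$ and a star center attains exactly 1 (the NetworkAnalyzer
convention, consistent with the magnitude of published cutoffs such as
0.0021). Closeness is the reciprocal of the mean shortest-path distance to
the *reachable* nodes only, so it is computed component-wise; an isolated
node gets 0. Edge confidence scores are never used as path weights — no
weighting rule is established for this screen, and confidence is not a
distance.

**The median screen.** Cutoffs are `degree_fold` × median degree (default
2) and the plain medians of betweenness and closeness, with the median of
an even-length list defined as the mean of the two middle values. All three
comparisons are strict (`>`), mirroring published cutoff statements of the
form "Degree > 46". Medians are computed over the network actually being
screened (normally the hub network): the phrase "all the network nodes"
is read as the nodes of that network, not of the larger CT-OT network.

**Hub extraction.** "First neighbors" are distance-1 neighbors *in the
CT-OT network*, not in the raw PPI, and the extracted subgraph is the full
induced subgraph (seed–seed, seed–neighbor and neighbor–neighbor edges),
which is what selection-based extraction in Cytoscape produces. Isolate
removal is applied to every constructed network. Extraction is monotone in
the seed set and idempotent, and both properties are tested.

**Over-representation.** For overlap $k$ between a query of size $n$ and a
set of size $K$ in a universe of size $N$, the raw p-value is the
hypergeometric upper tail $P(X \ge k)$; the default `"ease"` method
evaluates the same tail at $\max(k-1, 0)$ — the conservative one-removed
Fisher variant used by the DAVID server, chosen as default because the
workflow this package re-implements relied on DAVID scores (DAVID never
documents its background precisely, so published p-values are reference
points, not reproducible quantities). The universe defaults to the union
of all annotated genes in the collection; an explicit background can be
supplied. BH adjustment is applied across all scored sets. Sorting is
deterministic: adjusted p, raw p, fold enrichment (descending), name.
Gene Ontology namespaces are simply three separate collections run with
`adjust = "none"`; KEGG-style collections run with BH.

**Docking ratios.** Scores are normalized per target by the original
ligand's score; a missing score propagates as a missing cell (never 0).
Categories use half-open bands — weak $< 0.8 \le$ moderate $< 1.0 \le$
strong — a package convention (published usage of weak/moderate/strong
carries no numeric definition); the bands are configurable and
scale-invariant, since multiplying all scores for a target by $c > 0$
leaves ratios unchanged.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_score` | 0.4 | strict lower bound on PPI combined confidence (unitless, `[0,1]`; 0–1000 exports auto-detected and divided by 1000) |
| `degree_fold` | 2 | multiplier on the median degree in the key-target screen |
| `alpha` | 0.05 | strict significance threshold for pathway selection |
| `top_k` | 15 | pathways carried into disease-pathway mapping |
| `method` | `ease` | over-representation tail (`ease` or `hypergeometric`) |
| `adjust` | `BH` | multiple-testing adjustment |
| `ratio_cutoffs` | 0.8, 1.0 | weak/moderate and moderate/strong ratio boundaries |

## The synthetic world

`generate_dataset()` emulates the data shapes the pipeline consumes, at the
scale of the study it re-implements: a 500-gene interactome, 16 compounds
with 20 predicted targets each, 60 disease genes, 6 planted hubs entering
each target set with probability 0.9, a 20-set gene-set collection whose
planted set contains all planted hubs, and a 16 × 13 docking panel with a
ligand baseline of Uniform(80, 140) score units, strong pairs at 1.0–1.2 ×
baseline, background pairs at 0.5–0.9 ×, and 5% of cells missing.

The PPI generator is preferential attachment from a star seed on $m+1$
nodes, because empirical PPI degree distributions are heavy-tailed and the
median screen presupposes hubs; the construction forces exactly $m(n-m)$
edges, which makes the generator itself testable in closed form. Planted
hubs are the top-degree nodes with ties broken by gene id, so ground truth
is unambiguous. All randomness flows from one integer seed through derived
per-artifact sub-seeds; generators restore the caller's RNG state.

Two interpretation points, decided once:

* The generator's planted *common core* is the set of hubs that actually
  entered both target sets. With inclusion probability 0.9 per set, about
  half of all seeds leave at least one hub out of the disease list; in such
  a dataset that hub is not a common target and the screen cannot be
  faulted for missing it. The recovery suite therefore checks both
  readings: *all six* planted hubs recovered in at least 90 of 100 seeds
  (the stated 95-seed target with its stated ±5 stochastic tolerance), and
  all *planted-into-both-sets* hubs recovered in at least 95 of 100.
* The literal intersection of the compound-target union with the disease
  set also contains chance overlaps among uniformly drawn filler genes
  (tens of genes at these set sizes); the "planted common core in the
  6 ± 4 band" property refers to the planted core, which is what the truth
  record stores.

**What a green test establishes — and what it does not.** Recovery of
planted hubs shows the screen finds high-degree, high-centrality signal
when it exists and the generator's assumptions hold (scale-free topology,
hub-concentrated signal, uniform background). Real interactomes add study
bias, correlated annotation, literature-driven degree inflation and
identifier noise, none of which the generator emulates; green tests
validate the *procedure*, not any biological conclusion. Published
reference counts that depend on 2019-era database snapshots (network sizes,
DAVID p-values) are treated as output shapes only.

## Numerical and degenerate-input choices

* All threshold comparisons are strict; boundary behavior at 0.4, at the
  degree cutoff, and at `alpha = 0.05` is pinned by tests.
* Duplicate PPI rows keep the maximum score (deterministic, conservative);
  self-loops are dropped and counted.
* Betweenness of graphs with $N \le 2$ is 0; enrichment with zero overlap
  returns exactly 1; a screen that selects no key target does not abort the
  pipeline — downstream stages emit empty results and the report records
  zero counts.
* Identifier handling is uppercase-and-trim only; alias remapping is
  opt-in via an explicit two-column table, because silent symbol mapping is
  a classic source of irreproducibility.
* Reports record output paths relative to the output directory and contain
  no timestamps, so identical configuration and seed give byte-identical
  reports.

## Limitations

* STRING protein identifiers are assumed to be pre-mapped to gene symbols
  in the input files; no identifier translation service is consulted.
* The docking module consumes a score table; pose generation, receptor
  preparation and interaction diagrams are out of scope.
* Whether the original study's hub network retained neighbor–neighbor
  edges cannot be determined from its reported counts; the induced-subgraph
  reading adopted here is the common tool default.
* EASE/hypergeometric tails assume exchangeable genes; annotation
  correlation is not modelled.
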