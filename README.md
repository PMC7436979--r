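# netpharm

Network-pharmacology screening for multi-component formulas, as a tested R
package. Given (a) compound→target association tables, (b) a disease target
gene list, (c) a STRING-style PPI edge list, (d) gene-set collections in GMT
format, (e) a disease-associated pathway list, and (f) a docking-score
table, netpharm reproduces the standard screening workflow used to explain
how herbal formulas act on complex diseases:

* **common targets** — intersection of the compound-target union with the
  disease targets;
* **CT-OT network** — PPI subgraph induced on both target sets, edges kept
  with combined confidence strictly > 0.4 (0–1000 exports auto-detected),
  interaction-free nodes removed;
* **hub network** — common targets plus first neighbors, full induced
  subgraph, isolates removed;
* **key targets** — the median-threshold topological screen
  `deg(v) > 2·median(deg)`, `C_B(v) > median(C_B)`, `C_C(v) > median(C_C)`,
  with Brandes betweenness normalized by `(N−1)(N−2)/2` and closeness over
  reachable nodes (both computed from scratch, oracle-tested);
* **pathways** — hypergeometric / EASE over-representation
  (`P(X ≥ k)` for `X ~ Hypergeom(N, K, n)`; EASE evaluates the tail at
  `max(k−1, 0)`), BH adjustment, top-15 selection, mapping onto the disease
  pathway list;
* **networks & docking** — compound–key-target and
  compound–target–pathway graphs (GraphML/SIF/TSV export), and
  ligand-normalized LibDock-style score ratios
  `r = score(compound, T) / score(original ligand, T)` with
  weak (< 0.8) / moderate / strong (≥ 1.0) categories and a heat-map + CSV
  twin.

A seeded synthetic-data module generates a scale-free interactome with
planted hubs, target tables sharing a planted common core, a gene-set
collection with one planted enriched set, and a docking panel with planted
strong pairs — so the entire pipeline is testable offline and its power to
recover planted structure is itself under test.

## Worked example

```r
library(netpharm)

ds    <- generate_dataset(synthetic_config(seed = 42))
common <- common_targets(ds$ct, ds$dt)          # 27 genes (6 planted hubs + chance overlap)
ctot  <- build_ct_ot_network(ds$ct, ds$dt, ds$ppi, min_score = 0.4)
hub   <- extract_hub_network(ctot, common)
scr   <- screen_key_targets(centrality_table(hub))
scr
#> screening_result: 8 key target(s)
#>   cutoffs: degree > 4, betweenness > 5.15358e-05, closeness > 0.319444

enr <- enrich(scr$key_targets, ds$collection, method = "ease", adjust = "BH")
head(enr[, c("set_name", "k", "K", "p_raw", "p_adj")], 3)
#>     set_name k  K        p_raw        p_adj
#> 1 PW_PLANTED 6 26 0.0001162508 0.0009300064
#> 2 PW_RND_001 2 20 0.4078221626 1.0000000000
#> 3 PW_RND_010 1 18 1.0000000000 1.0000000000

map_disease_pathways(top_pathways(enr), ds$disease_pathways)$set_name
#> [1] "PW_PLANTED"

drm <- docking_ratios(ds$docking)
drm
#> docking_ratio_matrix: 16 compounds x 13 targets (10 missing)
round(drm$ratios[1:3, 1:3], 3)
#>       G0002 G0003 G0004
#> CMP01 0.875 0.669 0.569
#> CMP02    NA 1.102 0.525
#> CMP03 0.875 0.799 0.858
```

The 8 key targets include all 6 planted hubs; the planted gene set ranks
first (adjusted p = 9.3e-4) and is correctly mapped as the disease-related
pathway; `NA` cells are pairs for which no docking pose was generated —
missing, not zero.

The same run, end to end, from a config file:

```yaml
# run.yaml
simulate: {}        # or an `inputs:` block naming your own files
seed: 42
params: {min_score: 0.4, degree_fold: 2, alpha: 0.05, top_k: 15}
```

```sh
Rscript -e 'netpharm::netpharm_main()' run --config run.yaml --outdir out/
# or, after installation: <library>/netpharm/exec/netpharm run --config run.yaml
```

which writes `ctot.graphml`, `hub.graphml`, `key_targets.tsv`,
`enrichment.tsv`, `common_pathways.txt`, `ctp.graphml`, `ratios.csv` and a
deterministic `report.json` (identical config + seed ⇒ byte-identical
outputs). Subcommands `simulate`, `build-network`, `hub`, `screen`,
`enrich`, `ctp-net` and `dock-ratios` expose each stage separately.

## Scope

The pipeline consumes files; it does not query TCMSP, CTD, STRING, DAVID or
any other service, does not run docking, and does not attempt to reproduce
snapshot-dependent published counts (network sizes, DAVID p-values) —
see the methods vignette in `vignettes/` for the full design rationale.
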