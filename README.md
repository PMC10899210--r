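# dgnet

Disease gene networks from protein interactomes and developmental brain
expression.

Many pairs of brain disorders — Parkinson's disease (PD) and schizophrenia
(SZ) being a prominent example — share genetic risk, yet the mechanisms
behind that sharing are hard to read off GWAS hit lists. One productive
framing is *network medicine*: take the top disease-associated genes, expand
each list to its **interactome** (the seed genes plus all of their immediate
protein–protein interaction neighbors and the edges among them), and ask how
the two interactomes relate — how strongly they overlap, and whether their
genes organise into clusters with distinct spatiotemporal expression
identities in the developing brain. `dgnet` implements that pipeline as a
tested, reusable R package:

- **Interactome construction** from a gene–disease association (GDA) table
  and tab-delimited PPI edge tables (direct interactions `MI:0407` and
  physical associations `MI:0915`, optional confidence filtering).
- **Overlap statistics.** For gene sets of sizes K and n sharing k genes in
  a universe of N, the enrichment p-value is the hypergeometric upper tail
  P(X ≥ k), X ~ Hypergeom(N, K, n), evaluated in log space so that
  astronomically small tails (p ~ 1e-310) are exact, with fold enrichment
  kN/(Kn) and Benjamini–Hochberg control across interactome pairs.
- **Temporal clustering into DGNs.** Genes × (region, stage) matrices of
  log10 mean RPKM are clustered with Pearson-correlation distance
  (d = 1 − r, pairwise-complete) and average linkage (UPGMA); sub-clusters
  are labelled by their disease affiliation (SZ-unique / PD-unique /
  shared) via hypergeometric over-representation, and merged into **disease
  gene networks (DGNs)** when they share both the affiliation and the
  dominant PCA quadrant.
- **PCA quadrants.** Missing-value-tolerant PCA by iterative truncated-SVD
  imputation; genes are assigned to quadrants I–IV by the signs of their
  first two component scores, and quadrant × gene-set enrichment is
  reported with intersection percentages.
- **Enrichment profiles.** A generic ORA engine, −log10 p profile matrices
  (entities × gene sets), rank-based inverse-normal z-scores (Blom), and
  UPGMA co-clustering of profiles — the machinery behind "DGN1 clusters
  with DGN2, DGN3 with DGN4" style statements.
- **Topological modules.** Molecular-complex-style detection: vertices are
  weighted by k-core number × core density of their closed neighborhood,
  modules grow greedily around high-weight seeds, with haircut trimming of
  singly-connected members, and are annotated by ORA.
- **Synthetic data.** A generator that emulates the full input bundle (PPI
  table with planted near-clique modules and controlled interactome
  overlap, GDA table with tie injection, spatiotemporal expression with
  four planted temporal archetypes, GMT gene sets), so every stage is
  testable without database downloads.

## Worked example

The overlap between two interactomes of 3200 and 2662 genes sharing 1232
genes in a 17,992-gene universe:

```r
library(dgnet)
universe <- paste0("g", 1:17992)
overlap_stats(paste0("g", 1:3200), paste0("g", 1969:4630), universe)
#>   size_a size_b universe_size intersection expected fold_enrichment   p_value
#> 1   3200   2662         17992         1232    473.5           2.602 2.88e-310
```

A 2.6-fold enrichment over the 473.5 genes expected by chance, with a
log-space hypergeometric tail of 2.88e-310 — an overlap far beyond what
independent gene sets could produce.

The full clustering stage on synthetic data with four planted temporal
archetypes (800 genes, 10 regions, 8 stages, log-scale noise sd 0.3, 5%
dropout):

```r
cfg  <- synthetic_config(rng_seed = 1)
b    <- gen_synthetic_bundle(cfg)
m    <- assemble_matrix(b$expression, stage_levels = cfg$stages)
tree <- upgma_cluster(pearson_distance(m))
cl   <- cut_tree(tree, 4)
pca  <- svd_impute(scale_unit_variance(m), 2)
pca
#> <dgn_pca: 800 genes, 2 components (52.7% + 30.8% of variance), converged after 7 iteration(s)>
assign_dgn(cl, truth_affiliation_sets(b$truth),
           universe = b$truth$genes$gene, quadrants = assign_quadrants(pca))
#>   cluster n_genes affiliation adjusted_p dominant_quadrant dgn_id
#> 1       B     200   PD-unique  7.77e-194               III   DGN1
#> 2       C     200   SZ-unique   4.00e-75                 I   DGN2
#> 3       D     200      shared  7.77e-194                IV   DGN3
#> 4       A     200   SZ-unique   4.00e-75                II   DGN4
```

Each recovered cluster matches one planted archetype (adjusted Rand index
1.0 here), carries the planted disease affiliation with the hypergeometric
evidence shown, and occupies its own PCA quadrant. `run_dgn_pipeline()`
chains every stage (interactomes → overlap → matrix → clustering → DGNs →
quadrants → enrichment profiles → modules) from files on disk and writes
per-stage TSVs plus a JSON run manifest.

Plot helpers: `autoplot(pca)` (quadrant map), `plot_temporal_profiles()`,
`plot_profile_heatmap()`; `tidy()`/`glance()` methods cover the fitted
objects.

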