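---
title: "Disease gene networks: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disease gene networks: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dgnet)
```

This vignette is the package's own account of the science it implements:
the models and procedures, the tunable parameters and why their defaults
are what they are, what the synthetic-data generator does and does not
emulate, and the places where the design was genuinely open and a choice
had to be made.

## The pipeline at a glance

Starting from (a) a gene–disease association (GDA) table, (b) undirected
protein–protein interaction (PPI) edge tables, (c) long-format
spatiotemporal expression records, and (d) GMT gene-set collections, the
pipeline:

1. selects the top-k seed genes per disease by GDA score;
2. builds each disease **interactome** — seeds plus immediate PPI
   neighbors plus induced edges — and scores pairwise interactome overlap;
3. assembles a genes × (region, stage) matrix of log10 mean RPKM;
4. clusters genes by Pearson-correlation distance with UPGMA, cuts the
   tree into primary and sub-clusters, and labels sub-clusters by disease
   affiliation into **disease gene networks (DGNs)**;
5. extracts principal components by SVD with imputation and assigns genes
   to quadrants of the (PC1, PC2) plane;
6. runs hypergeometric over-representation analyses, assembles −log10 p
   enrichment-profile matrices, z-transforms and co-clusters them;
7. decomposes the PPI graph into densely interconnected topological
   modules.

## Overlap and enrichment statistics

All enrichment questions reduce to one test. For a query of n genes and a
set of K genes sharing k genes inside a universe of N, the p-value is the
hypergeometric upper tail

$$p = P(X \ge k), \qquad X \sim \mathrm{Hypergeom}(N, K, n),$$

with fold enrichment $kN/(Kn)$ (observed over expected intersection). The
tail is evaluated through `phyper(..., log.p = TRUE)` and exponentiated at
the end: interactome-scale overlaps produce tails around $10^{-310}$,
which underflow to zero in linear space but survive as denormals when the
computation stays logarithmic. `k = 0` short-circuits to $p = 1$ (the
whole tail). Multiple testing uses Benjamini–Hochberg step-up control
(`bh_adjust()`, a validated front for `stats::p.adjust`), with adjusted
p < 0.05 declared significant throughout.

The universe matters and is explicit everywhere. For interactome overlap
it defaults to every symbol incident to at least one retained PPI edge;
for collection-based ORA it defaults to the union of the collection's
genes. Both are configurable, because the right background depends on how
the gene sets were ascertained. Every tested set is intersected with the
universe before counting, which enforces $k \le \min(K, n) \le N$ by
construction.

## Expression matrix conventions

Replicate RPKM values measured at the same (gene, region, stage)
coordinate are averaged arithmetically, a mean of zero is treated as
unobserved (missing cell), and observed means are log10-transformed. Two
conventions here were genuinely open:

- **Zeros in replicate averaging.** Whether zero replicates enter the mean
  before the zero-to-missing rule is applied is ambiguous; the default lets
  them participate (a coordinate becomes missing only when *all*
  replicates are zero), preserving partial signal. The alternative —
  dropping zero replicates before averaging — is available as
  `zero_policy = "drop"`.
- **"Expressed in a region".** A gene belongs to a region's expression
  gene set when it exceeds the threshold (strictly) in *at least one*
  coordinate of the region; the aggregation rule is not forced by the data
  model, and any-coordinate is the permissive, stage-agnostic reading.
  Thresholds are strict (a gene at exactly logRPKM 2 with threshold 2 is
  out).

Stage ordering is always supplied as a vocabulary (`brainspan_stages()` by
default, labels ending in `pcw` being prenatal) and never inferred
lexically — "4mos" would otherwise sort before "8pcw".

## Clustering

Distances are $d = 1 - r$ with $r$ the Pearson correlation over
pairwise-complete positions (minimum 2 shared positions per pair; pairs
below that, and zero-variance profiles, are hard errors naming the genes —
silent NA propagation into a dendrogram is worse than failing). Trees are
built by UPGMA: iteratively merge the pair of clusters at the smallest
average pairwise distance, with that average as the merge height. The
implementation is the package's own — the Lance–Williams average-linkage
update with a vectorised minimum search, O(n²) per merge — for two
reasons: the tie rule (ties resolve to the lowest index pair, making the
tree deterministic) is explicit, and the suite can cross-check it against
both `stats::hclust(method = "average")` on tie-free inputs and a naive
O(n³) re-computation oracle. Heights are ultrametric (monotone along every
root path) and `cut_tree(k)` removes the k−1 highest merges; cluster ids
are assigned in dendrogram leaf order.

The number of clusters is a configuration choice (`k_primary = 2`,
`k_sub = 5` by default), not a height threshold: published sub-cluster
counts of this kind typically come from visual dendrogram inspection, and
an explicit k is the reproducible encoding of that judgment.

**DGN assignment.** Each sub-cluster is tested against each disease
affiliation set (SZ-unique / PD-unique / shared interactome membership),
BH-corrected across all (cluster × affiliation) tests; the most
significant affiliation below adjusted p 0.05 becomes the label, otherwise
the cluster is reported `unassigned`. Sub-clusters sharing a label — and,
when PCA quadrants are available, the same dominant quadrant — are merged
into one DGN. The merge rule generalises the observation that two
sub-clusters with the same affiliation, concentrated in the same quadrant,
and separated only by a low-variance component are not meaningfully
distinct entities.

## PCA with missing values

Rows (genes) are centered and scaled to unit variance over their
non-missing entries; scaling is row-wise by default because the object of
interest is the *shape* of each gene's spatiotemporal profile, not the
scale of any coordinate (a column-wise mode exists for the alternative
reading). Missing cells are initialised with column means, then the scheme
alternates truncated-SVD reconstruction with refilling of the missing
cells until the largest absolute change in any imputed cell falls below
`tol` (default 1e-6) or `max_iter` (default 500) is reached. On complete
data this is exactly one truncated SVD, and variance fractions equal
squared singular values over their total. The iteration converges
linearly; for near-singular problems (for example exact rank-1 completion)
the per-iteration change underestimates the remaining error, so precision
work should tighten `tol` — the suite's rank-1 recovery checks run at
`tol = 1e-9`, `max_iter = 5000`. Non-convergence is a warning plus a
`converged = FALSE` flag, not an error: a usable projection with a caveat
beats an aborted pipeline.

SVD component signs are arbitrary, so each component is oriented to make
its largest-magnitude loading positive, and the applied flips are
recorded — an external orientation (e.g. from a published figure) can be
matched by a post-hoc flip, which swaps quadrants I↔II and III↔IV without
changing any test statistic. Quadrants are I = (+,+), II = (−,+),
III = (−,−), IV = (+,−) on (PC1, PC2); exact zero scores resolve to the
positive side and are counted.

## Enrichment profiles and co-clustering

Profile matrices hold $-\log_{10} p$ per (gene set, entity) cell, with p
floored at 1e-300 to keep cells finite. Raw rather than adjusted p-values
populate the cells by default: the matrix is an *input to clustering*, not
an inference, and the monotone BH transform would only flatten
within-column contrast; a flag flips this. The "inverse normal
transformation" of such profiles is interpreted as the rank-based Blom
transform, $z = \Phi^{-1}\!\big((r - 3/8)/(m + 1/4)\big)$ with average
ranks for ties, applied per column (per entity) by default — it is
invariant to monotone rescaling, which makes the co-clustering robust to
the p-floor and to the raw-vs-adjusted choice. A plain standardisation is
provided (`method = "standardize"`) because the phrase is ambiguous in the
heat-map tooling this emulates; the rank-based reading is the default, not
a claim about the original tool's internals. Profiles are co-clustered by
reusing the Pearson/UPGMA machinery on rows and columns, reporting the
flat column grouping at k = 2.

## Topological modules

Vertex weight = (highest k-core number of the closed neighborhood) ×
(edge density of that highest k-core): members of a clique $K_m$ weigh
$m - 1$. Modules grow from the highest-weight unused seed (ties by vertex
name, so input order is irrelevant), admitting the seed's neighbors whose
weight strictly exceeds $(1 - \mathrm{vwp}) \times$ seed weight (default
vwp 0.2). The haircut (default on) iteratively removes members connected
to the module by a single edge, and removed vertices return to the seed
pool; fluff (default off) appends dense unused neighbors afterwards.
Modules are vertex-disjoint, at least 2 genes, connected, and ranked by
density × size.

One design point deserves emphasis: expansion here admits the *seed's*
neighborhood only, rather than recursing through neighbors-of-neighbors.
Recursive expansion cannot separate two equally dense cliques joined by a
bridge — every vertex of both cliques carries the same weight, so the
first complex swallows the whole graph. One-hop expansion with the haircut
decomposes that benchmark into the two cliques, which is the behaviour a
module decomposition of a disease interactome needs; the published
"molecular complex detection" heuristic this emulates recurses, and users
should expect coarser modules from tools that do. Module counts are
strongly parameter- and data-version-dependent; headline figures like "241
modules in the human interactome" are qualitative reference points, not
reproduction targets.

## The synthetic-data generator

The generator emits the full input bundle — PPI table, GDA table,
expression records, GMT sets, plus the planted truth — as pure functions
of a configuration and one RNG seed. Defaults define the desk-scale study
conditions used across the suite: 800 genes, 10 regions, 8 stages (3
prenatal), 40 seeds per disease with half shared, preferential-attachment
backbone (3 edges/vertex) with 3 planted near-cliques (12 genes, edge
probability 0.9), archetype means 2.5/0.5 log10-RPKM, noise sd 0.3,
dropout 5%, two replicates per coordinate. The archetype means and noise
were chosen to make recovery non-trivial but reliable at desk scale; they
are generator conventions, not estimates of any dataset.

Four temporal archetypes drive expression, tied to disease affiliations
(1, 2 → SZ-unique; 3 → PD-unique; 4 → shared):

| archetype | stages | regions |
|---|---|---|
| A1 | all | first half |
| A2 | postnatal | all |
| A3 | alternating postnatal | second half |
| A4 | prenatal | all |

Two structural choices matter. First, A1 ("consistently high across all
ages") carries a spatial restriction because a perfectly flat profile has
zero variance — Pearson-correlation distance would be undefined for its
noiseless form and pure noise otherwise. Second, A1 and A3 have *opposite*
spatial preferences: purely temporal archetypes would leave A2/A4 as an
antipodal pair on PC1 with no PC2 component, straddling a quadrant
boundary; the chosen geometry places the four archetypes in four distinct
PCA quadrants, which is also what lets the quadrant-based DGN merge rule
operate on this data. Candidate designs were compared by simulation before
the generator was frozen.

Seed genes additionally receive `affiliation_edges_per_seed = 8` extra PPI
edges wired to genes of their own affiliation. Without this, 1-hop
neighborhoods on a plain preferential-attachment backbone are
affiliation-random, and graph-derived SZ-unique/PD-unique/shared sets
would carry no relation to the expression archetypes — real disease
neighborhoods are assortative in exactly this sense. A corollary: with
`planted_overlap_fraction = 0`, hub sharing still produces more overlap
than the hypergeometric null expects, so "no planted overlap" means
*weak*, not calibrated-uniform, p-values.

What the generator does **not** emulate: region-specific covariance
structure, donor/batch effects, realistic degree-versus-expression
coupling, GDA score distributions, or annotation incompleteness. Passing
tests on this data demonstrate that the machinery recovers planted
structure under idealised noise — they say nothing about whether a given
real dataset contains such structure.

## Problem sizes and numerical conventions

The suite runs the clustering recovery at 800 genes × 80 coordinates over
20 seeds, oracle comparisons at 8 leaves × 100 matrices (UPGMA), all
hypergeometric configurations at N ≤ 12 against exhaustive enumeration,
and BH against a quadratic-time direct implementation on 1000 random
vectors — sizes chosen so each property is checked densely while the whole
suite stays in the low minutes. Result tables serialize doubles at 17
significant digits and are read back with a correctly-rounded parser, so
write→read→write cycles are bit-identical. Degenerate inputs fail loudly
and early: empty seed sets, unknown stage labels, zero-variance rows,
sub-minimum shared positions, p-values outside [0, 1], and out-of-range
parameters are all named errors rather than propagated NAs.

## Known limitations

- Gene identifiers are case-sensitive symbols in a single namespace; no
  alias mapping. Cross-database symbol collisions are the caller's
  problem, by design.
- The interactome model is static: one-hop neighborhood expansion, no
  edge weights beyond threshold filtering, no depletion tests.
- `cut_tree` encodes cluster counts, not cut heights; reproducing a
  published dendrogram's exact sub-cluster sizes additionally requires the
  original data versions, which count-based cutting cannot substitute for.
- Module detection is deterministic but heuristic; near-ties in vertex
  weights can flip module boundaries between data versions even at fixed
  parameters.
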