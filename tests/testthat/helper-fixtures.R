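# Small fixtures built in code at test time.

write_ppi_fixture <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(c("interactor_a\tinteractor_b\tmi_code\tsource_db\tscore", rows),
             path)
  path
}

write_gmt_fixture <- function(lines, path = tempfile(fileext = ".gmt")) {
  writeLines(lines, path)
  path
}

# Two K5 cliques joined by a single bridge edge a1-b1.
bridged_cliques_edges <- function() {
  k5a <- t(combn(paste0("a", 1:5), 2))
  k5b <- t(combn(paste0("b", 1:5), 2))
  tibble::tibble(gene_a = c(k5a[, 1], k5b[, 1], "a1"),
                 gene_b = c(k5a[, 2], k5b[, 2], "b1"))
}

syn_genes_for_test <- function(cfg) sprintf("G%04d", seq_len(cfg$n_genes))

# One temporal-clustering run of the synthetic study conditions; returns
# the recovered partition, truth, and DGN assignment pieces.
run_synthetic_recovery <- function(seed, k = 4, with_quadrants = FALSE) {
  cfg <- synthetic_config(rng_seed = seed)
  truth <- gen_truth(cfg)
  expr <- gen_expression(cfg, truth)$expression
  m <- suppressMessages(assemble_matrix(expr, stage_levels = cfg$stages))
  tree <- upgma_cluster(pearson_distance(m))
  cl <- cut_tree(tree, k)
  quad <- NULL
  if (with_quadrants) {
    pca <- svd_impute(scale_unit_variance(m), 2)
    quad <- suppressMessages(assign_quadrants(pca))
  }
  dgn <- suppressMessages(assign_dgn(cl, truth_affiliation_sets(truth),
                                     universe = truth$genes$gene,
                                     quadrants = quad))
  list(config = cfg, truth = truth, matrix = m, tree = tree,
       clusters = cl, dgn = dgn, quadrants = quad)
}

# Majority archetype of each recovered cluster.
cluster_archetypes <- function(clusters, truth) {
  arch <- truth$genes$archetype[match(clusters$item, truth$genes$gene)]
  vapply(unique(clusters$cluster), function(cl) {
    names(which.max(table(arch[clusters$cluster == cl])))
  }, character(1))
}
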