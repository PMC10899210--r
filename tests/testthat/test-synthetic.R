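test_that("generators are pure functions of the configuration", {
  cfg <- synthetic_config(rng_seed = 13)
  b1 <- gen_synthetic_bundle(cfg)
  b2 <- gen_synthetic_bundle(cfg)
  expect_identical(b1$edges, b2$edges)
  expect_identical(b1$gda, b2$gda)
  expect_identical(b1$expression, b2$expression)
  expect_identical(b1$gene_sets$sets, b2$gene_sets$sets)
  expect_identical(b1$truth$genes, b2$truth$genes)

  # a different seed changes the data
  b3 <- gen_synthetic_bundle(synthetic_config(rng_seed = 14))
  expect_false(identical(b1$edges, b3$edges))

  # the generators do not disturb the caller's RNG stream
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(gen_synthetic_bundle(cfg)); after <- runif(3)
  expect_identical(before, after)
})

test_that("emitted files validate against the package readers", {
  cfg <- synthetic_config(rng_seed = 13)
  b <- gen_synthetic_bundle(cfg)
  dir <- tempfile("bundle_")
  paths <- write_synthetic_bundle(b, dir)
  edges <- suppressMessages(read_ppi_table(paths[["ppi"]]))
  expect_equal(edges[, c("gene_a", "gene_b")],
               b$edges[, c("gene_a", "gene_b")])
  expr <- read_expression_long(paths[["expression"]])
  expect_equal(nrow(expr), nrow(b$expression))
  gs <- read_gmt(paths[["gene_sets"]])
  expect_equal(gs$sets, b$gene_sets$sets)
})

test_that("top-k selection on the emitted GDA table recovers the planted seeds", {
  cfg <- synthetic_config(rng_seed = 17)
  out <- gen_gda_table(cfg)
  for (d in c("SZ", "PD")) {
    sel <- select_top_seeds(out$gda, d, cfg$n_seeds_per_disease)
    expect_setequal(sel$gene, out$truth$seeds[[d]])
    # the injected tie at the cut is real: >= 3 genes share the cut score
    cut_score <- min(sel$gda_score)
    expect_gte(sum(out$gda$gda_score[out$gda$disease_id == d] == cut_score), 3)
    # row order invariance
    shuf <- out$gda[sample(nrow(out$gda)), ]
    expect_equal(select_top_seeds(shuf, d, cfg$n_seeds_per_disease)$gene,
                 sel$gene)
  }
})

test_that("planted interactome overlap drives the hypergeometric signal", {
  for (s in 1:3) {
    cfg <- synthetic_config(planted_overlap_fraction = 0.5, rng_seed = 100 + s)
    net <- gen_ppi_network(cfg)
    uni <- ppi_universe(net$edges)
    ia <- build_interactome(net$truth$seeds$SZ, net$edges, "SZ")
    ib <- build_interactome(net$truth$seeds$PD, net$edges, "PD")
    r <- overlap_stats(ia, ib, uni)
    expect_lt(r$p_value, 1e-10)

    cfg0 <- synthetic_config(planted_overlap_fraction = 0, rng_seed = 100 + s)
    net0 <- gen_ppi_network(cfg0)
    i0a <- build_interactome(net0$truth$seeds$SZ, net0$edges, "SZ")
    i0b <- build_interactome(net0$truth$seeds$PD, net0$edges, "PD")
    r0 <- overlap_stats(i0a, i0b, ppi_universe(net0$edges))
    expect_gt(r0$p_value, r$p_value) # far weaker without planted sharing
  }
})

test_that("noiseless expression makes archetype recovery exact", {
  cfg <- synthetic_config(noise_sd = 0, dropout_rate = 0, rng_seed = 19)
  truth <- gen_truth(cfg)
  expr <- gen_expression(cfg, truth)$expression
  m <- suppressMessages(assemble_matrix(expr, stage_levels = cfg$stages))
  cl <- cut_tree(upgma_cluster(pearson_distance(m)), 4)
  arch <- truth$genes$archetype[match(cl$item, truth$genes$gene)]
  expect_equal(mclust::adjustedRandIndex(cl$cluster, arch), 1)
})

test_that("decoy gene sets stay unenriched for archetype clusters", {
  cfg <- synthetic_config(rng_seed = 23)
  b <- gen_synthetic_bundle(cfg)
  a1 <- b$truth$genes$gene[b$truth$genes$archetype == "A1"]
  res <- hypergeom_ora(a1, b$gene_sets, universe = syn_genes_for_test(cfg))
  expect_lt(res$adjusted_p[res$set_id == "A1_signature"], 1e-10)
  decoys <- grepl("_decoy$", res$set_id)
  expect_true(mean(res$adjusted_p[decoys] > 0.05) >= 0.75)
})

test_that("configuration invariants are enforced", {
  expect_error(synthetic_config(archetype_fractions = c(0.5, 0.5, 0.2, 0.2)))
  expect_error(synthetic_config(planted_overlap_fraction = 1.5))
  expect_error(synthetic_config(stages = c("8pcw", "16pcw")),
               class = "dgnet_parameter_error")
  expect_error(synthetic_config(n_genes = 5))
})
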