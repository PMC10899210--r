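test_that("Pearson distance matches the direct formula and its limits", {
  m <- rbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(3, 2, 1), d = c(1, 2, 4),
             e = c(1, 3, 3))
  d <- as.matrix(pearson_distance(m))
  expect_equal(d["a", "b"], 0)              # perfect correlation
  expect_equal(d["a", "c"], 2)              # perfect anticorrelation
  r_de <- cor(c(1, 2, 4), c(1, 3, 3))
  expect_equal(d["d", "e"], 1 - r_de)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 5))
})

test_that("Pearson distance is invariant under positive affine transforms", {
  set.seed(41)
  m <- matrix(rnorm(50), 5, dimnames = list(paste0("g", 1:5), NULL))
  d1 <- as.matrix(pearson_distance(m))
  m2 <- m
  m2[2, ] <- 3.7 * m2[2, ] + 11
  m2[4, ] <- 0.01 * m2[4, ] - 2
  expect_equal(as.matrix(pearson_distance(m2)), d1, tolerance = 1e-12)
})

test_that("Pearson distance errors on degenerate pairs", {
  m <- rbind(a = c(1, 2, 3, 4), b = c(1, 1, 1, 1), c = c(0, 1, 0, 1))
  expect_error(pearson_distance(m), "zero-variance.*b",
               class = "dgnet_distance_error")

  m2 <- rbind(a = c(1, 2, NA, NA), b = c(NA, NA, 1, 2))
  expect_error(pearson_distance(m2), "fewer than 2",
               class = "dgnet_distance_error")
})

test_that("UPGMA reproduces hand traces", {
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  t2 <- upgma_cluster(d2)
  expect_equal(t2$height, 0.4)

  d3 <- matrix(c(0, 2, 6, 2, 0, 4, 6, 4, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- upgma_cluster(d3)
  expect_equal(t3$height, c(2, 5)) # ({A,B}, C) at (6 + 4)/2
  cl <- cut_tree(t3, 2)
  expect_equal(cl$cluster[cl$item == "A"], cl$cluster[cl$item == "B"])
  expect_false(cl$cluster[cl$item == "C"] == cl$cluster[cl$item == "A"])

  expect_error(upgma_cluster(matrix(0, 1, 1)), "at least 2")
})

test_that("UPGMA agrees with stats::hclust average linkage on tie-free inputs", {
  set.seed(42)
  for (i in 1:25) {
    d <- random_tie_free_dist(8)
    mine <- upgma_cluster(d)
    ref <- hclust(d, method = "average")
    expect_equal(mine$height, ref$height)
    expect_identical(mine$merge, ref$merge)
  }
})

test_that("UPGMA heights are monotone and cuts are nested refinements", {
  set.seed(43)
  for (i in 1:10) {
    n <- sample(5:12, 1)
    tree <- upgma_cluster(random_tie_free_dist(n))
    expect_true(all(diff(tree$height) >= -1e-12))
    for (k in 1:(n - 1)) {
      ck <- cut_tree(tree, k)$cluster
      ck1 <- cut_tree(tree, k + 1)$cluster
      # k+1 partition refines k: every k+1 cluster sits inside one k cluster
      expect_true(all(vapply(split(ck, ck1),
                             function(x) length(unique(x)) == 1, logical(1))))
    }
  }
})

test_that("cut_tree boundary cases and range checks", {
  tree <- upgma_cluster(random_tie_free_dist(6))
  expect_equal(unique(cut_tree(tree, 1)$cluster), "A")
  expect_equal(length(unique(cut_tree(tree, 6)$cluster)), 6)
  expect_error(cut_tree(tree, 0), class = "dgnet_parameter_error")
  expect_error(cut_tree(tree, 7), class = "dgnet_parameter_error")
})

test_that("a sub-cluster inside an affiliation set gets that label with minimal p", {
  clusters <- tibble::tibble(item = paste0("g", 1:30),
                             cluster = rep(c("A", "B", "C"), each = 10))
  sets <- list("SZ-unique" = paste0("g", 1:10),
               "PD-unique" = paste0("g", 11:20),
               "shared" = paste0("g", 21:30))
  res <- assign_dgn(clusters, sets, universe = paste0("g", 1:30))
  expect_equal(res$affiliation[match(c("A", "B", "C"), res$cluster)],
               c("SZ-unique", "PD-unique", "shared"))
  expect_true(all(res$adjusted_p < 0.05))
  expect_equal(sort(unique(res$dgn_id)), c("DGN1", "DGN2", "DGN3"))
})

test_that("clusters with no significant affiliation are reported unassigned", {
  set.seed(44)
  clusters <- tibble::tibble(item = paste0("g", 1:40),
                             cluster = rep(c("A", "B"), 20)) # interleaved
  sets <- list("SZ-unique" = paste0("g", 1:20),
               "shared" = paste0("g", 21:40))
  expect_message(res <- assign_dgn(clusters, sets, paste0("g", 1:40)),
                 "no significant affiliation")
  expect_true(all(res$affiliation == "unassigned"))
  expect_true(all(is.na(res$dgn_id)))
})

test_that("synthetic archetypes are recovered with correct DGN affiliations", {
  run <- run_synthetic_recovery(seed = 7, k = 4, with_quadrants = TRUE)
  arch <- run$truth$genes$archetype[match(run$clusters$item,
                                          run$truth$genes$gene)]
  expect_gte(mclust::adjustedRandIndex(run$clusters$cluster, arch), 0.9)
  modal <- cluster_archetypes(run$clusters, run$truth)
  expected <- c(A1 = "SZ-unique", A2 = "SZ-unique",
                A3 = "PD-unique", A4 = "shared")
  got <- setNames(run$dgn$affiliation, run$dgn$cluster)
  expect_equal(unname(got[names(modal)]), unname(expected[modal]))
  # four distinct DGNs once quadrants separate the two SZ-unique clusters
  expect_equal(length(unique(na.omit(run$dgn$dgn_id))), 4)
})

test_that("sub-clusters sharing affiliation and dominant quadrant merge into one DGN", {
  run <- run_synthetic_recovery(seed = 7, k = 4, with_quadrants = TRUE)
  # split the first cluster artificially into two sub-clusters
  cl <- run$clusters
  first <- cl$item[cl$cluster == "A"]
  cl$cluster[cl$item %in% first[seq_len(length(first) %/% 2)]] <- "A2"
  dgn <- suppressMessages(assign_dgn(cl, truth_affiliation_sets(run$truth),
                                     universe = run$truth$genes$gene,
                                     quadrants = run$quadrants))
  expect_equal(length(unique(na.omit(dgn$dgn_id))), 4)
  expect_equal(dgn$dgn_id[dgn$cluster == "A"], dgn$dgn_id[dgn$cluster == "A2"])
})
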