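test_that("unit variance scaling centers and scales rows", {
  m <- rbind(a = c(1, 2, 3), b = c(10, 20, 60))
  s <- scale_unit_variance(m)
  expect_equal(unname(s["a", ]), c(-1, 0, 1))
  expect_equal(mean(s["b", ]), 0)
  expect_equal(sd(s["b", ]), 1)
  # idempotence
  expect_equal(unclass(scale_unit_variance(s)), unclass(s), tolerance = 1e-12)
  expect_error(scale_unit_variance(rbind(cst = c(2, 2, 2))),
               class = "dgnet_validation_error")
})

test_that("svd_impute on complete data equals direct truncated SVD", {
  set.seed(51)
  m <- matrix(rnorm(80), 16, 5, dimnames = list(paste0("g", 1:16), NULL))
  p <- svd_impute(m, 2)
  expect_true(p$converged)
  sv <- svd(m)
  direct <- sv$u[, 1:2] %*% diag(sv$d[1:2])
  # orient the direct scores with the same largest-|loading| convention
  fl <- vapply(1:2, function(j) sign(sv$v[which.max(abs(sv$v[, j])), j]),
               numeric(1))
  direct <- sweep(direct, 2, fl, `*`)
  expect_equal(unname(p$scores), direct, tolerance = 1e-8)
  expect_equal(p$variance_explained, sv$d[1:2]^2 / sum(sv$d^2),
               tolerance = 1e-10)
})

test_that("svd_impute recovers masked entries of rank-1 matrices", {
  m <- matrix(c(1, 2, 3, 6), 2) # rank 1
  m[2, 2] <- NA
  p <- svd_impute(m, 1, tol = 1e-9, max_iter = 5000)
  recon <- p$scores %*% t(p$loadings)
  expect_equal(recon[2, 2], 6, tolerance = 1e-6)
  expect_true(p$converged)

  # deterministic: identical output on identical input
  p2 <- svd_impute(m, 1, tol = 1e-9, max_iter = 5000)
  expect_identical(p$scores, p2$scores)
})

test_that("non-convergence warns but still returns a result", {
  m <- matrix(c(1, 2, 3, 6), 2)
  m[2, 2] <- NA
  expect_warning(p <- svd_impute(m, 1, tol = 1e-12, max_iter = 3),
                 "did not converge")
  expect_false(p$converged)
  expect_true(all(is.finite(p$scores)))
})

test_that("n_components is bounded by the matrix dimensions", {
  expect_error(svd_impute(matrix(rnorm(8), 4, 2), 3),
               class = "dgnet_parameter_error")
})

test_that("quadrants follow the sign convention and flip symmetry", {
  fake <- function(scores) {
    rownames(scores) <- paste0("g", seq_len(nrow(scores)))
    colnames(scores) <- c("PC1", "PC2")
    structure(list(scores = scores, variance_explained = c(0.8, 0.1)),
              class = "dgn_pca")
  }
  sc <- rbind(c(1, 1), c(-1, 1), c(-1, -1), c(1, -1))
  q <- assign_quadrants(fake(sc))
  expect_equal(as.character(q$quadrant), c("I", "II", "III", "IV"))

  # flipping the sign of PC1 swaps I <-> II and III <-> IV
  q2 <- assign_quadrants(fake(sc %*% diag(c(-1, 1))))
  expect_equal(as.character(q2$quadrant), c("II", "I", "IV", "III"))

  # exact zeros resolve to the positive side
  expect_message(q0 <- assign_quadrants(fake(rbind(c(0, -1), c(0, 1)))),
                 "zero")
  expect_equal(as.character(q0$quadrant), c("IV", "I"))
})

test_that("each synthetic archetype concentrates in one distinct quadrant", {
  run <- run_synthetic_recovery(seed = 3, k = 4, with_quadrants = TRUE)
  arch <- run$truth$genes$archetype[match(run$quadrants$gene,
                                          run$truth$genes$gene)]
  tab <- table(arch, run$quadrants$quadrant)
  modal <- apply(tab, 1, function(r) colnames(tab)[which.max(r)])
  expect_equal(length(unique(modal)), 4)
  expect_true(all(apply(tab, 1, max) / rowSums(tab) > 0.9))
})

test_that("quadrant enrichment is exact for a set equal to a quadrant", {
  genes <- paste0("g", 1:40)
  fake <- structure(list(scores = matrix(
    c(rep(1, 10), rep(-1, 10), rep(-1, 10), rep(1, 10),
      rep(1, 10), rep(1, 10), rep(-1, 10), rep(-1, 10)),
    ncol = 2, dimnames = list(genes, c("PC1", "PC2")))),
    class = "dgn_pca")
  qa <- assign_quadrants(fake)
  sets <- list(exact_I = genes[1:10], decoy = genes[c(11, 21, 31, 1)])
  res <- quadrant_enrichment(qa, sets, universe = genes)
  hit <- res[res$quadrant == "I" & res$set_id == "exact_I", ]
  expect_equal(hit$k, 10)
  expect_equal(hit$percent_of_query, 100)
  expect_equal(hit$p_value, enum_hyper_tail(40, 10, 10, 10))
  # percent_of_set sums to 100 over quadrants for every set
  sums <- tapply(res$percent_of_set, res$set_id, sum)
  expect_equal(as.numeric(sums), rep(100, length(sums)))
})

test_that("quadrant x cluster intersections find planted enrichments", {
  run <- run_synthetic_recovery(seed = 5, k = 4, with_quadrants = TRUE)
  sets <- truth_affiliation_sets(run$truth)
  res <- suppressMessages(
    quadrant_enrichment(run$quadrants, sets,
                        universe = run$truth$genes$gene,
                        clusters = run$clusters))
  # in each quadrant, the dominant cluster is overwhelmingly of one
  # affiliation: its top hit must be the planted one
  modal <- cluster_archetypes(run$clusters, run$truth)
  expected <- c(A1 = "SZ-unique", A2 = "SZ-unique",
                A3 = "PD-unique", A4 = "shared")
  for (cl in names(modal)) {
    sub <- res[res$cluster == cl, ]
    sub <- sub[sub$n == max(sub$n), ] # the quadrant where the cluster lives
    top <- sub$set_id[which.min(sub$adjusted_p)]
    expect_equal(unname(top), unname(expected[modal[cl]]))
  }
})
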