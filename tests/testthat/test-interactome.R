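test_that("seed selection ranks by GDA score with lexicographic tie-break", {
  rec <- tibble::tibble(gene = c("G1", "G2", "G3", "G4"),
                        disease_id = "PD",
                        gda_score = c(0.9, 0.8, 0.8, 0.7))
  expect_equal(nrow(select_top_seeds(rec, "PD", 0)), 0)
  expect_equal(select_top_seeds(rec, "PD", 2)$gene, c("G1", "G2"))
  # beyond availability: everything, still sorted
  expect_equal(select_top_seeds(rec, "PD", 10)$gene, c("G1", "G2", "G3", "G4"))
  expect_error(select_top_seeds(rec, "PD", -1), class = "dgnet_parameter_error")
  expect_error(select_top_seeds(rec, "XX", 5), class = "dgnet_empty_set_error")
})

test_that("top-100 of a 200-record table matches a full-sort oracle", {
  set.seed(11)
  rec <- tibble::tibble(gene = sprintf("G%03d", sample(200)),
                        disease_id = "SZ",
                        gda_score = round(runif(200), 2)) # rounded: real ties
  got <- select_top_seeds(rec, "SZ", 100)$gene
  oracle <- rec[order(-rec$gda_score, rec$gene), ]$gene[1:100]
  expect_equal(got, oracle)
  # row order invariance
  shuf <- rec[sample(nrow(rec)), ]
  expect_equal(select_top_seeds(shuf, "SZ", 100)$gene, got)
})

test_that("interactome is seeds plus immediate neighbors with induced edges", {
  empty_edges <- tibble::tibble(gene_a = character(0), gene_b = character(0))
  it <- build_interactome("A", empty_edges, disease_id = "d")
  expect_equal(it$members, "A")
  expect_equal(nrow(it$edges), 0)

  edges <- tibble::tibble(gene_a = c("A", "B"), gene_b = c("B", "C"))
  it2 <- suppressMessages(build_interactome("A", edges, disease_id = "d"))
  expect_setequal(it2$members, c("A", "B"))
  expect_equal(nrow(it2$edges), 1) # only A-B is induced; C is 2 hops away
  expect_error(build_interactome(character(0), edges),
               class = "dgnet_empty_set_error")

  # seeds absent from the network stay as isolated members
  expect_message(it3 <- build_interactome(c("A", "Z"), edges, disease_id = "d"),
                 "isolated")
  expect_true("Z" %in% it3$members)
})

test_that("overlap_stats reproduces exact enumeration and closed forms", {
  uni <- paste0("g", 1:10)
  a <- paste0("g", 1:4)
  b <- paste0("g", c(3, 4, 5, 6, 7)) # k = 2? no: overlap {g3,g4} -> k=2
  r <- overlap_stats(a, b, uni)
  expect_equal(r$p_value, enum_hyper_tail(10, 4, 5, r$intersection))

  # the spec-level worked small case: N=10, K=4, n=5, k=3 -> 66/252
  b3 <- paste0("g", c(2, 3, 4, 5, 6))
  r3 <- overlap_stats(a, b3, uni)
  expect_equal(r3$intersection, 3)
  expect_equal(r3$p_value, 66 / 252)

  # disjoint sets: whole tail, fold zero
  rd <- overlap_stats(paste0("g", 1:3), paste0("g", 4:6), uni)
  expect_equal(rd$p_value, 1)
  expect_equal(rd$fold_enrichment, 0)
})

test_that("overlap_stats is symmetric, self-overlap fold is N/K, tail is monotone in k", {
  uni <- paste0("g", 1:50)
  a <- paste0("g", 1:20)
  b <- paste0("g", 11:35)
  expect_equal(overlap_stats(a, b, uni)$p_value, overlap_stats(b, a, uni)$p_value)

  rs <- overlap_stats(a, a, uni)
  expect_equal(rs$fold_enrichment, 50 / 20)

  ps <- vapply(0:10, function(k) {
    bk <- paste0("g", c(seq_len(k), if (k < 10) 40 + seq_len(10 - k)))
    overlap_stats(paste0("g", 1:10), bk, uni)$p_value
  }, numeric(1))
  expect_true(all(diff(ps) <= 1e-15))
})

test_that("empty universe is rejected", {
  expect_error(overlap_stats("a", "b", character(0)),
               class = "dgnet_parameter_error")
})

test_that("cross-disorder validation flags only the planted overlap", {
  set.seed(21)
  uni <- sprintf("g%04d", 1:2000)
  shared <- sample(uni, 300)
  ia <- structure(list(disease_id = "A", seeds = "s",
                       members = union(shared, sample(uni, 400)),
                       edges = tibble::tibble()), class = "interactome")
  ib <- structure(list(disease_id = "B", seeds = "s",
                       members = union(shared, sample(uni, 400)),
                       edges = tibble::tibble()), class = "interactome")
  ic <- structure(list(disease_id = "C", seeds = "s",
                       members = sample(uni, 600),
                       edges = tibble::tibble()), class = "interactome")
  res <- cross_disorder_validation(list(ia, ib, ic), uni)
  expect_equal(res$significant[res$disease_b == "B"], TRUE)
  expect_equal(res$significant[res$disease_b == "C"], FALSE)

  # identical interactomes: k = K = n and fold = N/K
  rid <- overlap_stats(ia, ia, uni)
  expect_equal(rid$intersection, rid$size_a)
  expect_equal(rid$fold_enrichment, rid$universe_size / rid$size_a)

  expect_error(cross_disorder_validation(list(ia, ia), uni), "duplicate")
})
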