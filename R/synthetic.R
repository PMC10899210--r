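# Synthetic-data generator. Emits gene-disease association tables, PPI
# edge tables, long-format spatiotemporal expression and gene-set
# collections with the statistical structure the pipeline assumes:
# a scale-free-ish PPI backbone with planted near-clique modules,
# seed sets with controlled interactome overlap, and four temporal
# expression archetypes tied to disease affiliations
# (1, 2 -> SZ-unique; 3 -> PD-unique; 4 -> shared).
#
# Every generator is a pure function of (config, rng_seed): RNG state is
# scoped with withr::with_seed and the caller's stream is untouched.

#' Synthetic study configuration
#'
#' Defaults define the desk-scale study conditions used throughout the
#' test-suite: 800 genes, 10 brain regions, 8 stages (3 prenatal), log-RPKM
#' archetype means 2.5 (active) / 0.5 (inactive), Gaussian noise sd 0.3 on
#' the log scale, 5% dropout, two replicates per coordinate, and two
#' disease seed sets sharing half their seeds.
#'
#' @param n_genes Number of genes (>= 10).
#' @param n_seeds_per_disease Seed genes per disease.
#' @param planted_overlap_fraction Fraction of seeds shared between the two
#'   diseases, in \[0, 1\]; controls the expected interactome overlap.
#' @param attachment_edges_per_node Edges added per vertex in the
#'   preferential-attachment backbone.
#' @param n_regions Number of brain regions.
#' @param stages Ordered stage labels; names ending `pcw` are prenatal.
#' @param archetype_fractions Length-4 fractions of genes per temporal
#'   archetype; must sum to 1.
#' @param noise_sd Gaussian noise sd on the log10 scale.
#' @param dropout_rate Probability a measured cell is emitted as RPKM 0.
#' @param affiliation_edges_per_seed Extra PPI edges wired from each seed
#'   gene to genes of its own disease affiliation, making interactome
#'   neighborhoods affiliation-assortative (as disease neighborhoods are),
#'   so graph-derived affiliation sets correlate with the expression
#'   archetypes.
#' @param n_planted_modules,module_size,module_edge_prob Planted
#'   near-clique modules in the PPI graph.
#' @param rng_seed Integer seed; all generators derive their streams from
#'   it.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 800,
                             n_seeds_per_disease = 40,
                             planted_overlap_fraction = 0.5,
                             attachment_edges_per_node = 3,
                             n_regions = 10,
                             stages = c("8pcw", "16pcw", "24pcw", "4mos",
                                        "1yr", "4yrs", "13yrs", "40yrs"),
                             archetype_fractions = c(0.25, 0.25, 0.25, 0.25),
                             noise_sd = 0.3,
                             dropout_rate = 0.05,
                             affiliation_edges_per_seed = 8,
                             n_planted_modules = 3,
                             module_size = 12,
                             module_edge_prob = 0.9,
                             rng_seed = 1L) {
  stopifnot(n_genes >= 10,
            length(archetype_fractions) == 4,
            abs(sum(archetype_fractions) - 1) < 1e-8,
            all(archetype_fractions >= 0),
            planted_overlap_fraction >= 0, planted_overlap_fraction <= 1,
            dropout_rate >= 0, dropout_rate <= 1,
            noise_sd >= 0)
  if (!any(grepl("pcw$", stages)) || all(grepl("pcw$", stages))) {
    abort("stages must contain both prenatal (pcw) and postnatal labels",
          class = "dgnet_parameter_error")
  }
  structure(list(n_genes = n_genes,
                 n_seeds_per_disease = n_seeds_per_disease,
                 planted_overlap_fraction = planted_overlap_fraction,
                 attachment_edges_per_node = attachment_edges_per_node,
                 n_regions = n_regions, stages = stages,
                 archetype_fractions = archetype_fractions,
                 noise_sd = noise_sd, dropout_rate = dropout_rate,
                 affiliation_edges_per_seed = affiliation_edges_per_seed,
                 n_planted_modules = n_planted_modules,
                 module_size = module_size,
                 module_edge_prob = module_edge_prob,
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_config")
}

syn_genes <- function(config) sprintf("G%04d", seq_len(config$n_genes))

# Archetype activity pattern over (region, stage) coordinates.
# 1: all stages, first half of the regions (high across all ages,
#    spatially restricted so the profile has variance under correlation)
# 2: postnatal stages, all regions (infancy to adulthood)
# 3: alternating postnatal stages, second half of the regions
#    (stage-peaked, with a regional preference distinct from archetype 1
#    so the four archetypes occupy four distinct PCA quadrants)
# 4: prenatal stages, all regions
archetype_pattern <- function(config) {
  prenatal <- grepl("pcw$", config$stages)
  post_idx <- which(!prenatal)
  regions <- sprintf("R%02d", seq_len(config$n_regions))
  coords <- tidyr::expand_grid(region = regions, stage = config$stages)
  half1 <- regions[seq_len(ceiling(config$n_regions / 2))]
  half2 <- setdiff(regions, half1)
  peaked <- config$stages[post_idx[seq(1, length(post_idx), by = 2)]]
  act <- list(
    A1 = coords$region %in% half1,
    A2 = coords$stage %in% config$stages[!prenatal],
    A3 = coords$stage %in% peaked & coords$region %in% half2,
    A4 = coords$stage %in% config$stages[prenatal]
  )
  list(coords = coords, active = act)
}

#' Generate the synthetic truth labels
#'
#' Assigns each gene a temporal archetype (per the configured fractions)
#' and the derived disease affiliation (archetypes 1 and 2 are SZ-unique,
#' 3 is PD-unique, 4 is shared), and selects the planted seed and module
#' genes used by the other generators.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `synthetic_truth`: `genes` tibble (`gene`,
#'   `archetype`, `affiliation`), `seeds` (named list of seed vectors for
#'   diseases `SZ` and `PD`), `modules` (list of planted module gene
#'   vectors).
#' @export
gen_truth <- function(config) {
  withr::with_seed(config$rng_seed + 101L, {
    genes <- syn_genes(config)
    n <- config$n_genes
    counts <- floor(config$archetype_fractions * n)
    counts[1] <- counts[1] + (n - sum(counts))
    archetype <- sample(rep(paste0("A", 1:4), counts))
    affiliation <- c(A1 = "SZ-unique", A2 = "SZ-unique",
                     A3 = "PD-unique", A4 = "shared")[archetype]
    gt <- tibble(gene = genes, archetype = archetype,
                 affiliation = unname(affiliation))

    ns <- config$n_seeds_per_disease
    n_shared <- round(config$planted_overlap_fraction * ns)
    shared_pool <- gt$gene[gt$affiliation == "shared"]
    sz_pool <- gt$gene[gt$archetype %in% c("A1", "A2")]
    pd_pool <- gt$gene[gt$archetype == "A3"]
    shared_seeds <- sample(shared_pool, min(n_shared, length(shared_pool)))
    sz_seeds <- c(shared_seeds,
                  sample(sz_pool, min(ns - length(shared_seeds), length(sz_pool))))
    pd_seeds <- c(shared_seeds,
                  sample(pd_pool, min(ns - length(shared_seeds), length(pd_pool))))

    module_genes <- split(
      sample(genes, config$n_planted_modules * config$module_size),
      rep(seq_len(config$n_planted_modules), each = config$module_size))
    names(module_genes) <- sprintf("MOD%d", seq_len(config$n_planted_modules))

    structure(list(genes = gt,
                   seeds = list(SZ = sz_seeds, PD = pd_seeds),
                   modules = module_genes),
              class = "synthetic_truth")
  })
}

#' Generate a synthetic PPI edge table
#'
#' A preferential-attachment backbone (degree-heterogeneous, emulating a
#' protein-interaction network) plus planted near-clique modules whose
#' membership is recorded in the truth object. Edge attributes (MI code,
#' source, confidence) are drawn so the table exercises the readers.
#'
#' @param config A [synthetic_config()].
#' @param truth Output of [gen_truth()]; generated if `NULL`.
#' @return List with `edges` (tibble `gene_a`, `gene_b`, `mi_code`,
#'   `source_db`, `confidence`) and `truth`.
#' @export
gen_ppi_network <- function(config, truth = NULL) {
  truth <- truth %||% gen_truth(config)
  withr::with_seed(config$rng_seed + 202L, {
    genes <- syn_genes(config)
    g <- igraph::sample_pa(config$n_genes,
                           m = config$attachment_edges_per_node,
                           directed = FALSE)
    el <- igraph::as_edgelist(g)
    edges <- tibble(gene_a = genes[el[, 1]], gene_b = genes[el[, 2]])
    for (mod in truth$modules) {
      pairs <- t(combn(mod, 2))
      keep <- stats::runif(nrow(pairs)) < config$module_edge_prob
      edges <- bind_rows(edges, tibble(gene_a = pairs[keep, 1],
                                       gene_b = pairs[keep, 2]))
    }
    # affiliation-assortative wiring: each seed gene gains edges to genes
    # of its own affiliation, so 1-hop disease neighborhoods carry the
    # planted affiliation signal
    k_aff <- config$affiliation_edges_per_seed
    if (k_aff > 0) {
      aff <- setNames(truth$genes$affiliation, truth$genes$gene)
      for (s in unique(unlist(truth$seeds))) {
        pool <- setdiff(truth$genes$gene[truth$genes$affiliation == aff[[s]]], s)
        tgt <- sample(pool, min(k_aff, length(pool)))
        edges <- bind_rows(edges, tibble(gene_a = s, gene_b = tgt))
      }
    }
    a <- pmin(edges$gene_a, edges$gene_b)
    b <- pmax(edges$gene_a, edges$gene_b)
    edges <- distinct(tibble(gene_a = a, gene_b = b))
    edges <- filter(edges, .data$gene_a != .data$gene_b)
    edges$mi_code <- sample(c("MI:0407", "MI:0915"), nrow(edges), replace = TRUE)
    edges$source_db <- sample(c("synthdb1", "synthdb2"), nrow(edges), replace = TRUE)
    edges$confidence <- round(stats::runif(nrow(edges), 0.4, 1), 3)
    list(edges = arrange(edges, .data$gene_a, .data$gene_b), truth = truth)
  })
}

#' Generate a synthetic gene-disease association table
#'
#' Scores are drawn so the planted seed genes occupy the top-k by GDA
#' score for their disease, with a 3-way tie injected at the cut whose
#' decoy gene sorts lexicographically after the tied seeds — so top-k
#' selection with the lexicographic tie rule recovers the planted seeds
#' exactly while still exercising the rule.
#'
#' @inheritParams gen_ppi_network
#' @return List with `gda` (tibble `gene`, `disease_id`, `gda_score`,
#'   diseases `SZ` and `PD`) and `truth`.
#' @export
gen_gda_table <- function(config, truth = NULL) {
  truth <- truth %||% gen_truth(config)
  withr::with_seed(config$rng_seed + 303L, {
    genes <- syn_genes(config)
    one_disease <- function(disease) {
      seeds <- sort(truth$seeds[[disease]])
      ns <- length(seeds)
      others <- setdiff(genes, seeds)
      scores_seed <- round(seq(0.95, 0.6, length.out = ns), 4)
      scores_other <- round(stats::runif(length(others), 0.01, 0.5), 4)
      tab <- tibble(gene = c(seeds, others),
                    disease_id = disease,
                    gda_score = c(scores_seed, scores_other))
      # tie at the cut: last two seeds + one decoy share a score; the decoy
      # sorts lexicographically after both so it loses the tie-break
      cut_seeds <- sort(seeds)[c(ns - 1, ns)]
      decoy_pool <- others[others > max(cut_seeds)]
      if (length(decoy_pool) > 0) {
        decoy <- sample(decoy_pool, 1)
        tie_score <- min(tab$gda_score[tab$gene %in% cut_seeds])
        tab$gda_score[tab$gene %in% c(cut_seeds, decoy)] <- tie_score
      }
      tab
    }
    list(gda = bind_rows(one_disease("SZ"), one_disease("PD")), truth = truth)
  })
}

#' Generate synthetic long-format expression records
#'
#' Each gene expresses its archetype's activity pattern: mean log10-RPKM
#' 2.5 in active coordinates and 0.5 elsewhere, plus Gaussian noise
#' (`noise_sd`, log scale), emitted as linear RPKM with two replicates per
#' (gene, region, stage) coordinate; `dropout_rate` of replicate
#' measurements are zeroed (unexpressed).
#'
#' @inheritParams gen_ppi_network
#' @return List with `expression` (tibble `gene`, `region`, `stage`,
#'   `rpkm`) and `truth`.
#' @export
gen_expression <- function(config, truth = NULL) {
  truth <- truth %||% gen_truth(config)
  pat <- archetype_pattern(config)
  withr::with_seed(config$rng_seed + 404L, {
    n_coord <- nrow(pat$coords)
    recs <- purrr::map_dfr(1:2, function(rep_i) {
      purrr::map_dfr(paste0("A", 1:4), function(arch) {
        gg <- truth$genes$gene[truth$genes$archetype == arch]
        if (length(gg) == 0) return(NULL)
        mean_log <- ifelse(pat$active[[arch]], 2.5, 0.5)
        vals <- matrix(stats::rnorm(length(gg) * n_coord,
                                    mean = rep(mean_log, each = length(gg)),
                                    sd = config$noise_sd),
                       nrow = length(gg))
        rpkm <- 10^vals
        rpkm[matrix(stats::runif(length(rpkm)) < config$dropout_rate,
                    nrow = length(gg))] <- 0
        tibble(gene = rep(gg, times = n_coord),
               region = rep(pat$coords$region, each = length(gg)),
               stage = rep(pat$coords$stage, each = length(gg)),
               rpkm = as.vector(rpkm))
      })
    })
    list(expression = arrange(recs, .data$gene, .data$region, .data$stage),
         truth = truth)
  })
}

#' Generate synthetic gene-set collections
#'
#' One signature set per planted topological module and per temporal
#' archetype, plus size-matched decoy sets of random genes, for testing
#' module annotation and enrichment calibration.
#'
#' @inheritParams gen_ppi_network
#' @return List with `gene_sets` (a [gene_set_collection()]) and `truth`.
#' @export
gen_gene_sets <- function(config, truth = NULL) {
  truth <- truth %||% gen_truth(config)
  withr::with_seed(config$rng_seed + 505L, {
    genes <- syn_genes(config)
    sets <- list()
    for (m in names(truth$modules)) {
      sets[[paste0(m, "_signature")]] <- truth$modules[[m]]
      sets[[paste0(m, "_decoy")]] <- sample(genes, length(truth$modules[[m]]))
    }
    for (a in paste0("A", 1:4)) {
      gg <- truth$genes$gene[truth$genes$archetype == a]
      sets[[paste0(a, "_signature")]] <- gg
      sets[[paste0(a, "_decoy")]] <- sample(genes, length(gg))
    }
    list(gene_sets = gene_set_collection(sets, name = "synthetic_sets"),
         truth = truth)
  })
}

#' Affiliation gene sets from the synthetic truth
#'
#' @param truth A `synthetic_truth`.
#' @return Named list of gene vectors (`SZ-unique`, `PD-unique`, `shared`).
#' @export
truth_affiliation_sets <- function(truth) {
  split(truth$genes$gene, truth$genes$affiliation)
}

#' Generate the full synthetic input bundle
#'
#' Runs every generator under one configuration and returns all inputs
#' plus the planted truth.
#'
#' @param config A [synthetic_config()].
#' @return List with `config`, `truth`, `edges`, `gda`, `expression`,
#'   `gene_sets`.
#' @export
gen_synthetic_bundle <- function(config = synthetic_config()) {
  truth <- gen_truth(config)
  list(config = config,
       truth = truth,
       edges = gen_ppi_network(config, truth)$edges,
       gda = gen_gda_table(config, truth)$gda,
       expression = gen_expression(config, truth)$expression,
       gene_sets = gen_gene_sets(config, truth)$gene_sets)
}

#' Write a synthetic bundle to disk
#'
#' Emits the PPI table (TSV), GDA table (TSV), expression records (TSV),
#' gene sets (GMT) and the truth labels (JSON) in the formats the package
#' readers consume.
#'
#' @param bundle Output of [gen_synthetic_bundle()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_synthetic_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(ppi = file.path(dir, "ppi.tsv"),
             gda = file.path(dir, "gda.tsv"),
             expression = file.path(dir, "expression.tsv"),
             gene_sets = file.path(dir, "gene_sets.gmt"),
             truth = file.path(dir, "truth.json"))
  edges <- rename(bundle$edges, interactor_a = "gene_a", interactor_b = "gene_b",
                  score = "confidence")
  readr::write_tsv(edges, paths[["ppi"]], progress = FALSE)
  readr::write_tsv(bundle$gda, paths[["gda"]], progress = FALSE)
  readr::write_tsv(bundle$expression, paths[["expression"]], progress = FALSE)
  write_gmt(bundle$gene_sets, paths[["gene_sets"]])
  jsonlite::write_json(list(genes = bundle$truth$genes,
                            seeds = bundle$truth$seeds,
                            modules = bundle$truth$modules),
                       paths[["truth"]], auto_unbox = FALSE)
  invisible(paths)
}
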