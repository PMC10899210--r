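# End-to-end orchestration: interactomes -> overlap -> expression matrix ->
# temporal clustering -> DGN assignment -> PCA quadrants -> ORA ->
# enrichment profiles -> profile co-clustering -> topological modules.
# Every stage writes its outputs as TSV under the run directory together
# with a JSON manifest (parameters, input hashes, package version), so a
# rerun with the same configuration is bit-identical for deterministic
# stages.

#' Pipeline configuration
#'
#' Collects the input paths and stage parameters of a full run. Defaults
#' mirror the study conditions: top-100 seed genes per disease, MI codes
#' restricted to direct interaction / physical association, two primary and
#' five sub-clusters, 2 principal components, vertex weight percentage 0.2
#' with haircut.
#'
#' @param ppi_path,gda_path,expression_path,gene_sets_path Input file
#'   paths (PPI TSV, GDA TSV, long expression TSV/CSV, GMT).
#' @param out_dir Output directory for stage outputs and the manifest.
#' @param diseases Character vector (length 2) of disease ids whose
#'   interactomes are built and compared.
#' @param k_seeds Seeds per disease (default 100).
#' @param mi_filter,min_confidence Passed to [read_ppi_table()].
#' @param k_primary,k_sub Cluster counts for the primary and sub-cluster
#'   cuts.
#' @param n_components PCA components.
#' @param pca_coords Optional coordinate subset (`region|stage` labels) for
#'   the PCA stage; `NULL` uses all coordinates.
#' @param profile_mode z-transform mode for [inverse_normal_z()].
#' @param vwp,haircut,fluff MCODE-style module parameters.
#' @param stage_levels Ordered stage vocabulary.
#' @param rng_seed Seed recorded in the manifest (the pipeline stages are
#'   deterministic; the seed is threaded to any stochastic add-on).
#' @return A list of class `dgn_pipeline_config`.
#' @export
dgn_pipeline_config <- function(ppi_path, gda_path, expression_path,
                                gene_sets_path = NULL,
                                out_dir = tempfile("dgn_run_"),
                                diseases = c("SZ", "PD"),
                                k_seeds = 100,
                                mi_filter = c("MI:0407", "MI:0915"),
                                min_confidence = NULL,
                                k_primary = 2, k_sub = 5,
                                n_components = 2,
                                pca_coords = NULL,
                                profile_mode = "per_column",
                                vwp = 0.2, haircut = TRUE, fluff = FALSE,
                                stage_levels = brainspan_stages(),
                                rng_seed = 1L) {
  structure(as.list(environment()), class = "dgn_pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Checks file existence and parameter ranges without running anything.
#'
#' @param config A [dgn_pipeline_config()].
#' @return Tibble of issues (`field`, `problem`); zero rows when clean.
#' @export
validate_pipeline_config <- function(config) {
  issues <- list()
  note <- function(field, problem) {
    issues[[length(issues) + 1]] <<- tibble(field = field, problem = problem)
  }
  for (f in c("ppi_path", "gda_path", "expression_path")) {
    if (is.null(config[[f]]) || !file.exists(config[[f]])) {
      note(f, "file does not exist")
    }
  }
  if (!is.null(config$gene_sets_path) && !file.exists(config$gene_sets_path)) {
    note("gene_sets_path", "file does not exist")
  }
  if (config$k_seeds < 0) note("k_seeds", "must be >= 0")
  if (config$vwp < 0 || config$vwp > 1) note("vwp", "must be in [0, 1]")
  if (config$k_primary < 1) note("k_primary", "must be >= 1")
  if (config$k_sub < config$k_primary) note("k_sub", "must be >= k_primary")
  if (config$n_components < 2) note("n_components", "must be >= 2")
  if (length(config$diseases) != 2) note("diseases", "exactly 2 disease ids required")
  if (length(issues) == 0) {
    tibble(field = character(0), problem = character(0))
  } else {
    bind_rows(issues)
  }
}

#' Run the full disease-gene-network pipeline
#'
#' Executes every stage in order and writes each stage's table under
#' `config$out_dir` along with `manifest.json` recording the parameters,
#' input MD5 hashes and package version. Fails fast with the stage name on
#' any stage error.
#'
#' @param config A [dgn_pipeline_config()].
#' @return Invisibly, a list with every stage result and `out_dir`.
#' @export
run_dgn_pipeline <- function(config) {
  issues <- validate_pipeline_config(config)
  if (nrow(issues) > 0) {
    abort(paste0("invalid pipeline config: ",
                 paste(sprintf("%s (%s)", issues$field, issues$problem),
                       collapse = "; ")),
          class = "dgnet_config_error")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            class = "dgnet_stage_error", parent = e)
    })
  }
  out <- function(name) file.path(config$out_dir, name)

  edges <- stage("read_ppi", read_ppi_table(config$ppi_path,
                                            mi_filter = config$mi_filter,
                                            min_confidence = config$min_confidence))
  gda <- stage("read_gda", {
    g <- readr::read_tsv(config$gda_path, show_col_types = FALSE, progress = FALSE)
    stopifnot(all(c("gene", "disease_id", "gda_score") %in% names(g)))
    g
  })
  universe <- ppi_universe(edges)

  interactomes <- stage("build_interactomes", lapply(config$diseases, function(d) {
    build_interactome(select_top_seeds(gda, d, config$k_seeds), edges,
                      disease_id = d)
  }))
  members_union <- Reduce(union, lapply(interactomes, `[[`, "members"))
  affiliation_sets <- stage("affiliations", {
    m1 <- interactomes[[1]]$members
    m2 <- interactomes[[2]]$members
    sets <- list(setdiff(m1, m2), setdiff(m2, m1), intersect(m1, m2))
    names(sets) <- c(paste0(config$diseases[1], "-unique"),
                     paste0(config$diseases[2], "-unique"), "shared")
    sets[lengths(sets) > 0]
  })

  overlap <- stage("overlap",
                   cross_disorder_validation(interactomes, universe))
  write_results(overlap, out("overlap.tsv"))

  expr <- stage("read_expression", read_expression_long(config$expression_path))
  mat <- stage("assemble_matrix",
               assemble_matrix(expr, gene_filter = members_union,
                               stage_levels = config$stage_levels))
  write_results(as_tibble(mat), out("expression_matrix.tsv"))

  dist <- stage("pearson_distance", pearson_distance(mat, axis = "genes"))
  tree <- stage("upgma", upgma_cluster(dist))
  primary <- stage("cut_primary", cut_tree(tree, config$k_primary))
  sub <- stage("cut_sub", cut_tree(tree, config$k_sub))
  write_results(left_join(rename(primary, primary_cluster = "cluster"),
                          rename(sub, sub_cluster = "cluster"), by = "item"),
                out("clusters.tsv"))
  write_results(tibble(left = tree$merge[, 1], right = tree$merge[, 2],
                       height = tree$height),
                out("merge_tree.tsv"))

  scaled <- stage("scale", scale_unit_variance(select_coords(mat, config$pca_coords)))
  pca <- stage("pca", svd_impute(scaled, n_components = config$n_components))
  quad <- stage("quadrants", assign_quadrants(pca))
  write_results(quad, out("quadrants.tsv"))

  dgn <- stage("assign_dgn",
               assign_dgn(sub, affiliation_sets, universe = members_union,
                          quadrants = quad))
  write_results(dgn, out("dgn_assignment.tsv"))

  profiles <- NULL
  modules <- NULL
  annotations <- NULL
  if (!is.null(config$gene_sets_path)) {
    sets <- stage("read_gmt", read_gmt(config$gene_sets_path))
    dgn_ids <- unique(dgn$dgn_id[!is.na(dgn$dgn_id)])
    ora <- stage("ora", purrr::map_dfr(dgn_ids, function(id) {
      cls <- dgn$cluster[which(dgn$dgn_id == id)]
      genes <- sub$item[sub$cluster %in% cls]
      mutate(hypergeom_ora(genes, sets), query_id = id, .before = 1)
    }))
    write_results(ora, out("dgn_enrichment.tsv"))
    profiles <- stage("profiles", {
      pm <- build_profile_matrix(ora)
      z <- inverse_normal_z(pm, mode = config$profile_mode)
      list(profile = pm, z = z,
           clusters = if (ncol(z) >= 2) cluster_profiles(z) else NULL)
    })
    write_results(as_tibble(profiles$z, rownames = "set_id"), out("profile_z.tsv"))

    modules <- stage("modules", find_modules(edges, vwp = config$vwp,
                                             haircut = config$haircut,
                                             fluff = config$fluff))
    write_results(select(tidyr::unnest(modules, "genes"),
                         all_of(c("module_id", "genes", "score"))),
                  out("modules.tsv"))
    if (nrow(modules) > 0) {
      annotations <- stage("annotate_modules",
                           annotate_modules(modules, sets, universe))
      write_results(annotations, out("module_annotations.tsv"))
    }
  }

  manifest <- list(
    package = "dgnet",
    version = as.character(utils::packageVersion("dgnet")),
    rng_seed = config$rng_seed,
    parameters = config[c("diseases", "k_seeds", "mi_filter", "min_confidence",
                          "k_primary", "k_sub", "n_components", "profile_mode",
                          "vwp", "haircut", "fluff")],
    inputs = as.list(tools::md5sum(stats::na.omit(c(
      config$ppi_path, config$gda_path, config$expression_path,
      config$gene_sets_path %||% NA_character_))))
  )
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")

  invisible(list(out_dir = config$out_dir, edges = edges,
                 interactomes = interactomes, overlap = overlap,
                 matrix = mat, tree = tree, clusters = sub, dgn = dgn,
                 pca = pca, quadrants = quad, profiles = profiles,
                 modules = modules, annotations = annotations,
                 manifest = manifest))
}

# Restrict an expr_matrix to a coordinate subset (by "region|stage" label).
select_coords <- function(matrix, coords = NULL) {
  if (is.null(coords)) return(matrix)
  miss <- setdiff(coords, colnames(matrix))
  if (length(miss) > 0) {
    abort(sprintf("unknown coordinate(s): %s", paste(miss, collapse = ", ")))
  }
  keep <- colnames(matrix) %in% coords
  out <- unclass(matrix)[, keep, drop = FALSE]
  co <- attr(matrix, "coords")
  structure(out, coords = co[keep, , drop = FALSE],
            dropped_genes = attr(matrix, "dropped_genes"),
            class = class(matrix))
}
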