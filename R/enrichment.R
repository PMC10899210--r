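# Generic over-representation analysis, Benjamini-Hochberg control,
# -log10(p) enrichment-profile matrices with inverse-normal z-scores, and
# co-clustering of profiles across entities (DGNs, external interactomes).

#' Hypergeometric over-representation analysis
#'
#' Tests a query gene set against every set of a collection within a
#' universe: `p = P(X >= k)` for `X ~ Hypergeometric(N, K, n)` with
#' `K` the set size, `n` the query size and `k` their overlap, all after
#' intersection with the universe. P-values are Benjamini-Hochberg
#' corrected across the collection.
#'
#' @param query Character vector of query genes (or data frame with a
#'   `gene` column).
#' @param sets A [gene_set_collection()] or named list of gene sets.
#' @param universe Background gene universe; defaults to the union of all
#'   genes in the collection.
#'
#' @return Tibble with one row per set: `set_id`, `k`, `K`, `n`, `N`,
#'   `fold_enrichment`, `p_value`, `adjusted_p`.
#' @export
hypergeom_ora <- function(query, sets, universe = NULL) {
  if (inherits(sets, "gene_set_collection")) sets <- sets$sets
  stopifnot(is.list(sets), length(sets) > 0, !is.null(names(sets)))
  universe <- unique(as.character(universe %||% unlist(sets, use.names = FALSE)))
  N <- length(universe)
  q <- intersect(as_gene_set(query), universe)
  if (length(q) == 0) {
    abort("query is empty after intersection with the universe",
          class = "dgnet_empty_set_error")
  }
  res <- purrr::map_dfr(names(sets), function(sid) {
    s <- intersect(sets[[sid]], universe)
    k <- length(intersect(q, s))
    K <- length(s); nn <- length(q)
    lp <- if (k == 0) 0 else phyper(k - 1, K, N - K, nn,
                                    lower.tail = FALSE, log.p = TRUE)
    tibble(set_id = sid, k = k, K = K, n = nn, N = N,
           fold_enrichment = if (K * nn > 0) k * N / (K * nn) else NA_real_,
           p_value = exp(lp))
  })
  res$adjusted_p <- bh_adjust(res$p_value)
  res
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate control: p-values are sorted
#' ascending, multiplied by the number of tests and divided by their rank,
#' then made monotone from the largest rank down and capped at 1. Values
#' are returned in the original order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1]", class = "dgnet_parameter_error")
  }
  p.adjust(p_values, method = "BH")
}

#' Assemble an enrichment-profile matrix
#'
#' Builds the gene-sets x entities matrix of `-log10(p)` used for profile
#' co-clustering: rows are gene sets (e.g. brain regions), columns are
#' entities (DGNs, external interactomes). P-values are floored at 1e-300
#' before the log so cells stay finite. Missing (row, column) tests become
#' 0 with a note; duplicated tests are an error.
#'
#' @param results Tibble of enrichment results with columns `query_id`
#'   (entity), `set_id` and `p_value` (use `adjusted_p` by renaming it in,
#'   if adjusted profiles are wanted).
#' @param p_floor Lower floor applied to p-values (default 1e-300).
#' @return Numeric matrix (sets x entities) of `-log10(p)`.
#' @export
build_profile_matrix <- function(results, p_floor = 1e-300) {
  need <- c("query_id", "set_id", "p_value")
  stopifnot(all(need %in% names(results)))
  if (anyDuplicated(results[c("query_id", "set_id")])) {
    abort("duplicate (set_id, query_id) enrichment results",
          class = "dgnet_format_error")
  }
  rows <- unique(results$set_id)
  cols <- unique(results$query_id)
  m <- matrix(0, length(rows), length(cols), dimnames = list(rows, cols))
  if (nrow(results) < length(rows) * length(cols)) {
    inform(sprintf("build_profile_matrix: %d missing test(s) set to 0",
                   length(rows) * length(cols) - nrow(results)))
  }
  m[cbind(match(results$set_id, rows), match(results$query_id, cols))] <-
    -log10(pmax(results$p_value, p_floor))
  m
}

#' Rank-based inverse normal transformation
#'
#' Maps each vector of the matrix onto standard normal quantiles using
#' Blom offsets: `z = qnorm((r - 3/8) / (m + 1/4))` with `r` the ascending
#' rank (ties receive their average rank) and `m` the vector length. The
#' transform is invariant to monotone rescaling of its input. An all-equal
#' vector maps to all zeros with a warning. A plain standardisation
#' (`(x - mean) / sd`) is available as `method = "standardize"`.
#'
#' @param matrix Numeric matrix of `-log10(p)` values.
#' @param mode Which vectors to transform: `"per_column"` (per entity,
#'   default), `"per_row"`, or `"global"`.
#' @param method `"rank"` (Blom, default) or `"standardize"`.
#' @return Matrix of z-scores, same shape and dimnames.
#' @export
inverse_normal_z <- function(matrix, mode = c("per_column", "per_row", "global"),
                             method = c("rank", "standardize")) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  m <- unclass(matrix)
  tf <- function(x) {
    if (length(unique(x)) == 1) {
      warn("inverse_normal_z: all-equal vector mapped to zeros")
      return(rep(0, length(x)))
    }
    if (method == "rank") {
      r <- rank(x, ties.method = "average")
      qnorm((r - 3 / 8) / (length(x) + 1 / 4))
    } else {
      (x - mean(x)) / sd(x)
    }
  }
  out <- switch(mode,
    per_column = apply(m, 2, tf),
    per_row = t(apply(m, 1, tf)),
    global = matrix(tf(as.vector(m)), nrow(m), ncol(m))
  )
  dimnames(out) <- dimnames(m)
  out
}

#' Co-cluster enrichment profiles
#'
#' Hierarchically clusters both the rows (gene sets) and the columns
#' (entities) of a z-score profile matrix with Pearson-correlation
#' distance and UPGMA, and reports the flat column grouping at
#' `k = k_columns` — e.g. the split of DGNs into two families.
#'
#' @param z Z-score matrix from [inverse_normal_z()] (finite values).
#' @param k_columns Number of flat column groups to report (default 2).
#' @return A list with `row_tree`, `col_tree` (`upgma` objects) and
#'   `column_groups` (tibble `item`, `cluster`).
#' @export
cluster_profiles <- function(z, k_columns = 2) {
  stopifnot(all(is.finite(z)))
  row_tree <- upgma_cluster(pearson_distance(z, axis = "genes"))
  col_tree <- upgma_cluster(pearson_distance(z, axis = "coordinates"))
  list(row_tree = row_tree, col_tree = col_tree,
       column_groups = cut_tree(col_tree, k_columns))
}
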