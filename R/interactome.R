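# Disease interactome construction and overlap statistics.
#
# An interactome here is a seed gene set plus every immediate PPI neighbor
# of a seed, together with all edges induced among those members. Overlap
# between two interactomes is scored with a one-sided hypergeometric tail
# computed in log space, which stays accurate down to p ~ 1e-310.

#' Select top seed genes by gene-disease association score
#'
#' Ranks the gene-disease association (GDA) records of one disease by score
#' (descending) and returns the top `k` genes. Ties at the cut are broken by
#' ascending lexicographic gene symbol so that exactly `min(k, available)`
#' genes are returned deterministically.
#'
#' @param records Tibble of GDA records with columns `gene`, `disease_id`,
#'   `gda_score` (scores in \[0, 1\]).
#' @param disease_id Disease identifier to select records for.
#' @param k Number of seed genes requested (non-negative).
#'
#' @return A tibble with columns `gene`, `disease_id`, `gda_score`, `rank`,
#'   sorted by descending score then symbol.
#' @export
select_top_seeds <- function(records, disease_id, k) {
  stopifnot(is.data.frame(records))
  if (length(k) != 1 || is.na(k) || k < 0) {
    abort("k must be a single non-negative integer", class = "dgnet_parameter_error")
  }
  rec <- filter(records, .data$disease_id == !!disease_id)
  if (nrow(rec) == 0) {
    abort(sprintf("no GDA records for disease '%s'", disease_id),
          class = "dgnet_empty_set_error")
  }
  if (anyDuplicated(rec$gene)) {
    abort(sprintf("duplicate (gene, disease_id) records for disease '%s'", disease_id))
  }
  if (any(!is.finite(rec$gda_score))) abort("non-finite GDA score")
  rec <- arrange(rec, desc(.data$gda_score), .data$gene)
  out <- head(rec, n = min(k, nrow(rec)))
  mutate(select(out, all_of(c("gene", "disease_id", "gda_score"))),
         rank = row_number())
}

#' Build a disease interactome from seeds and a PPI edge table
#'
#' Members are the seeds plus every gene adjacent to a seed; the edge set is
#' the subgraph induced by the members on the full edge table. Seeds absent
#' from the PPI network are retained as isolated members (they still carry
#' expression signal downstream) and counted in a message.
#'
#' @param seeds Character vector of seed symbols, or the tibble returned by
#'   [select_top_seeds()].
#' @param edges Tibble of undirected, deduplicated edges as returned by
#'   [read_ppi_table()] (columns `gene_a`, `gene_b`, ...).
#' @param disease_id Disease label attached to the interactome; defaults to
#'   the `disease_id` column of `seeds` when present.
#'
#' @return An object of class `interactome`: a list with `disease_id`,
#'   `seeds`, `members` and `edges` (induced edge tibble).
#' @export
build_interactome <- function(seeds, edges, disease_id = NULL) {
  if (is.data.frame(seeds)) {
    if (is.null(disease_id) && "disease_id" %in% names(seeds)) {
      disease_id <- seeds$disease_id[1]
    }
    seeds <- seeds$gene
  }
  seeds <- unique(as.character(seeds))
  if (length(seeds) == 0) {
    abort("empty seed set", class = "dgnet_empty_set_error")
  }
  stopifnot(all(c("gene_a", "gene_b") %in% names(edges)))
  touch_a <- edges$gene_a %in% seeds
  touch_b <- edges$gene_b %in% seeds
  neighbors <- unique(c(edges$gene_b[touch_a], edges$gene_a[touch_b]))
  members <- union(seeds, neighbors)
  induced <- filter(edges, .data$gene_a %in% members & .data$gene_b %in% members)
  isolated <- setdiff(seeds, unique(c(edges$gene_a, edges$gene_b)))
  if (length(isolated) > 0) {
    inform(sprintf("build_interactome: %d seed(s) absent from the PPI network kept as isolated members",
                   length(isolated)))
  }
  structure(list(disease_id = disease_id %||% NA_character_,
                 seeds = seeds, members = members, edges = induced),
            class = "interactome")
}

#' @export
print.interactome <- function(x, ...) {
  cat(sprintf("<interactome '%s': %d seeds, %d members, %d induced edges>\n",
              x$disease_id, length(x$seeds), length(x$members), nrow(x$edges)))
  invisible(x)
}

#' @method tidy interactome
#' @export
tidy.interactome <- function(x, ...) {
  tibble(gene = x$members, disease_id = x$disease_id,
         is_seed = x$members %in% x$seeds)
}

#' @method glance interactome
#' @export
glance.interactome <- function(x, ...) {
  tibble(disease_id = x$disease_id, n_seeds = length(x$seeds),
         n_members = length(x$members), n_edges = nrow(x$edges))
}

#' Gene universe of a PPI edge table
#'
#' All symbols incident to at least one retained edge; the default
#' background for interactome overlap testing.
#'
#' @param edges Edge tibble (`gene_a`, `gene_b`).
#' @return Character vector of gene symbols.
#' @export
ppi_universe <- function(edges) {
  sort(unique(c(edges$gene_a, edges$gene_b)))
}

as_gene_set <- function(x) {
  if (inherits(x, "interactome")) return(x$members)
  if (is.data.frame(x)) return(unique(as.character(x$gene)))
  unique(as.character(x))
}

#' Hypergeometric overlap between two gene sets
#'
#' One-sided enrichment test of the intersection of two gene sets within a
#' universe: `p = P(X >= k)` where `X ~ Hypergeometric(N, K, n)`, with
#' `K = |A|`, `n = |B|`, `k = |A intersect B|` after intersecting both sets
#' with the universe. The tail is evaluated in log space so that extreme
#' overlaps (p around 1e-310) do not underflow to zero.
#'
#' @param set_a,set_b Gene sets: character vectors, `interactome` objects or
#'   data frames with a `gene` column.
#' @param universe Background gene universe (character vector); both sets
#'   are intersected with it before testing.
#'
#' @return A one-row tibble: `size_a` (K), `size_b` (n), `universe_size`
#'   (N), `intersection` (k), `expected` (K·n/N), `fold_enrichment`
#'   (k·N/(K·n)), `p_value`, `log10_p` and `adjusted_p` (NA; filled by
#'   [cross_disorder_validation()]).
#' @export
#' @examples
#' overlap_stats(paste0("g", 1:3200), paste0("g", 1969:4630),
#'               paste0("g", 1:17992))
overlap_stats <- function(set_a, set_b, universe) {
  universe <- unique(as.character(as_gene_set(universe)))
  N <- length(universe)
  if (N == 0) abort("empty universe", class = "dgnet_parameter_error")
  a <- intersect(as_gene_set(set_a), universe)
  b <- intersect(as_gene_set(set_b), universe)
  K <- length(a)
  n <- length(b)
  k <- length(intersect(a, b))
  expected <- K * n / N
  fold <- if (expected > 0) k / expected else NA_real_
  if (k == 0) {
    log_p <- 0 # the whole tail: P(X >= 0) = 1
  } else {
    log_p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE)
  }
  tibble(size_a = K, size_b = n, universe_size = N, intersection = k,
         expected = expected, fold_enrichment = fold,
         p_value = exp(log_p), log10_p = log_p / log(10),
         adjusted_p = NA_real_)
}

#' Cross-disorder interactome overlap validation
#'
#' Tests the overlap of a focal interactome against every other interactome
#' in a list, applying Benjamini-Hochberg correction across that family of
#' pairwise tests, and flags pairs significant at adjusted p < 0.05.
#'
#' @param interactomes List of `interactome` objects with distinct
#'   `disease_id`s.
#' @param universe Background gene universe (character vector).
#' @param focal Disease id of the focal interactome; defaults to the first.
#'
#' @return A tibble with one row per (focal, other) pair: `disease_a`,
#'   `disease_b`, the [overlap_stats()] columns, `adjusted_p` and
#'   `significant`.
#' @export
cross_disorder_validation <- function(interactomes, universe, focal = NULL) {
  stopifnot(length(interactomes) >= 2)
  ids <- vapply(interactomes, function(x) x$disease_id, character(1))
  if (anyDuplicated(ids)) abort("duplicate disease_ids in interactome list")
  focal <- focal %||% ids[1]
  if (!focal %in% ids) abort(sprintf("focal disease '%s' not in list", focal))
  others <- setdiff(ids, focal)
  fi <- interactomes[[which(ids == focal)]]
  res <- purrr::map_dfr(others, function(id) {
    oi <- interactomes[[which(ids == id)]]
    mutate(overlap_stats(fi, oi, universe),
           disease_a = focal, disease_b = id, .before = 1)
  })
  res$adjusted_p <- bh_adjust(res$p_value)
  res$significant <- res$adjusted_p < 0.05
  res
}
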