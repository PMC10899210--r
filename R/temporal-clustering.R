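# Hierarchical clustering of spatiotemporal expression profiles and
# assignment of disease-affiliation labels to the resulting sub-clusters.
#
# Distances are 1 - Pearson correlation over pairwise-complete positions;
# trees are built with average linkage (UPGMA), implemented here so the
# merge tie rule (lowest index pair) is explicit and deterministic.

#' Pearson correlation distance
#'
#' Computes `d = 1 - r` between rows (genes) or columns (coordinates) of an
#' expression matrix, where `r` is the Pearson correlation over
#' pairwise-complete positions. Values lie in \[0, 2\]. Pairs sharing fewer
#' than 2 non-missing positions, and profiles with zero variance over the
#' shared positions, are errors (the offending items are named).
#'
#' @param matrix Numeric matrix (typically an `expr_matrix`); rows are
#'   genes, columns coordinates.
#' @param axis `"genes"` (distance between rows, default) or
#'   `"coordinates"` (between columns).
#' @param min_shared Minimum number of shared non-missing positions per
#'   pair (default 2).
#'
#' @return A `stats::dist` object with item labels.
#' @export
pearson_distance <- function(matrix, axis = c("genes", "coordinates"),
                             min_shared = 2) {
  axis <- match.arg(axis)
  m <- unclass(matrix)
  if (axis == "genes") m <- t(m)
  # m now has items in columns
  items <- colnames(m) %||% as.character(seq_len(ncol(m)))
  if (ncol(m) < 2) abort("need at least 2 items to compute distances")
  obs <- !is.na(m)
  shared <- crossprod(obs)
  off <- upper.tri(shared)
  if (any(shared[off] < min_shared)) {
    bad <- which(shared < min_shared & off, arr.ind = TRUE)[1, ]
    abort(sprintf("items '%s' and '%s' share fewer than %d non-missing positions",
                  items[bad[1]], items[bad[2]], min_shared),
          class = "dgnet_distance_error")
  }
  r <- suppressWarnings(cor(m, use = "pairwise.complete.obs"))
  if (anyNA(r[off])) {
    bad <- which(is.na(r) & off, arr.ind = TRUE)
    nm <- unique(items[as.vector(bad)])
    abort(sprintf("zero-variance profile over shared positions involving: %s",
                  paste(head(nm, 5), collapse = ", ")),
          class = "dgnet_distance_error")
  }
  d <- 1 - r
  diag(d) <- 0
  d[d < 0] <- 0 # guard against -eps from rounding at r = 1
  stats::as.dist(d)
}

#' UPGMA (average linkage) hierarchical clustering
#'
#' Iteratively merges the pair of clusters with the smallest average
#' pairwise distance; the height of a merge is that average distance
#' (Lance-Williams update for average linkage), giving an ultrametric tree
#' with monotone non-decreasing heights. Tied candidate pairs are resolved
#' to the lowest index pair, so results are deterministic.
#'
#' @param dist A `stats::dist` object or symmetric distance matrix with
#'   zero diagonal.
#' @return An object of class `c("upgma", "hclust")`, compatible with
#'   [stats::cutree()] and `plot()`.
#' @export
upgma_cluster <- function(dist) {
  d <- as.matrix(dist)
  n <- nrow(d)
  if (n < 2) abort("need at least 2 items to cluster")
  if (!isTRUE(all.equal(d, t(d))) || any(diag(d) != 0)) {
    abort("distance matrix must be symmetric with zero diagonal")
  }
  labels <- rownames(d) %||% as.character(seq_len(n))

  size <- rep(1L, n)
  id <- -seq_len(n) # hclust encoding: negatives are singletons
  active <- rep(TRUE, n)
  # only the upper triangle is live; everything else is masked with Inf so
  # the closest pair is a single which.min away
  work <- d
  work[lower.tri(work, diag = TRUE)] <- Inf
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)

  for (step in seq_len(n - 1)) {
    # which.min scans column-major, so ties resolve to the lowest index
    # pair (smallest column, then smallest row): deterministic
    idx <- which.min(work)
    i <- (idx - 1L) %% n + 1L
    j <- (idx - 1L) %/% n + 1L
    best <- work[i, j]

    pair <- c(id[i], id[j])
    merge[step, ] <- pair[order(pair >= 0, abs(pair))] # hclust row convention
    height[step] <- best
    # average-linkage update: d(new, k) = (ni*d(i,k) + nj*d(j,k))/(ni+nj)
    ni <- size[i]; nj <- size[j]
    ks <- which(active)
    ks <- ks[ks != i & ks != j]
    if (length(ks) > 0) {
      dik <- work[cbind(pmin(ks, i), pmax(ks, i))]
      djk <- work[cbind(pmin(ks, j), pmax(ks, j))]
      work[cbind(pmin(ks, i), pmax(ks, i))] <- (ni * dik + nj * djk) / (ni + nj)
    }
    work[j, ] <- Inf
    work[, j] <- Inf
    active[j] <- FALSE
    size[i] <- ni + nj
    id[i] <- step
  }

  order <- tree_leaf_order(merge)
  structure(list(merge = merge, height = height, order = order,
                 labels = labels, method = "average",
                 dist.method = "pearson", call = match.call()),
            class = c("upgma", "hclust"))
}

# Leaf order by in-order traversal of the merge tree (left subtree first).
tree_leaf_order <- function(merge) {
  n <- nrow(merge) + 1
  walk_iter <- function(root) {
    out <- integer(0)
    stack <- list(root)
    while (length(stack) > 0) {
      node <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      if (node < 0) {
        out <- c(out, -node)
      } else {
        stack <- c(stack, list(merge[node, 2]), list(merge[node, 1]))
      }
    }
    out
  }
  walk_iter(n - 1)
}

#' Cut a dendrogram into k clusters
#'
#' Removes the `k - 1` highest merges of the tree and returns the resulting
#' cluster memberships. Cluster ids are letters (A, B, ...) assigned in
#' dendrogram leaf order, matching how sub-clusters are labelled on a
#' clustered heat map; for `k > 26` ids are `C01`, `C02`, ...
#'
#' @param tree An `upgma`/`hclust` object.
#' @param k Number of clusters, `1 <= k <= n`.
#' @return Tibble with columns `item` and `cluster`.
#' @export
cut_tree <- function(tree, k) {
  n <- length(tree$labels)
  if (k < 1 || k > n) abort("k out of range", class = "dgnet_parameter_error")
  raw <- cutree(tree, k = k)
  # relabel clusters by first appearance along the dendrogram leaf order
  leaf_seq <- raw[tree$order]
  lev <- unique(leaf_seq)
  ids <- if (k <= 26) LETTERS[seq_len(k)] else sprintf("C%02d", seq_len(k))
  tibble(item = tree$labels,
         cluster = ids[match(raw, lev)])
}

#' Assign disease gene network (DGN) labels to sub-clusters
#'
#' Tests each sub-cluster for over-representation of each disease
#' affiliation set (e.g. SZ-unique / PD-unique / shared interactome genes)
#' with a hypergeometric test, Benjamini-Hochberg corrected across all
#' (cluster x affiliation) tests. Each cluster is labelled with its most
#' significant affiliation at adjusted p < 0.05, or `"unassigned"`.
#' Clusters sharing a label — and, when quadrant assignments are supplied,
#' the same dominant PCA quadrant — are merged into one DGN; DGNs are
#' numbered in dendrogram cluster order.
#'
#' @param clusters Tibble from [cut_tree()] (`item`, `cluster`).
#' @param affiliation_sets Named list (or [gene_set_collection()]) of
#'   affiliation gene sets partitioning the interactome-union genes.
#' @param universe Background gene universe.
#' @param quadrants Optional tibble from [assign_quadrants()] (`gene`,
#'   `quadrant`), used for the merge rule.
#'
#' @return A tibble with one row per sub-cluster: `cluster`, `n_genes`,
#'   `affiliation`, the enrichment evidence (`k`, `K`, `n`, `N`,
#'   `p_value`, `adjusted_p`, `fold_enrichment`), `dominant_quadrant`
#'   (NA without `quadrants`) and `dgn_id`.
#' @export
assign_dgn <- function(clusters, affiliation_sets, universe, quadrants = NULL) {
  if (inherits(affiliation_sets, "gene_set_collection")) {
    affiliation_sets <- affiliation_sets$sets
  }
  stopifnot(is.list(affiliation_sets), !is.null(names(affiliation_sets)))
  universe <- unique(as.character(universe))
  cl_ids <- unique(clusters$cluster)

  tests <- purrr::map_dfr(cl_ids, function(cl) {
    genes <- intersect(clusters$item[clusters$cluster == cl], universe)
    purrr::map_dfr(names(affiliation_sets), function(aff) {
      s <- intersect(affiliation_sets[[aff]], universe)
      k <- length(intersect(genes, s))
      K <- length(s); nn <- length(genes); N <- length(universe)
      lp <- if (k == 0) 0 else phyper(k - 1, K, N - K, nn,
                                      lower.tail = FALSE, log.p = TRUE)
      tibble(cluster = cl, affiliation = aff, k = k, K = K, n = nn, N = N,
             p_value = exp(lp),
             fold_enrichment = if (K * nn > 0) k * N / (K * nn) else NA_real_)
    })
  })
  tests$adjusted_p <- bh_adjust(tests$p_value)

  best <- tests |>
    group_by(.data$cluster) |>
    arrange(.data$adjusted_p, .data$p_value, .data$affiliation, .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup()
  best$affiliation[best$adjusted_p >= 0.05] <- "unassigned"
  if (any(best$affiliation == "unassigned")) {
    inform(sprintf("assign_dgn: cluster(s) with no significant affiliation: %s",
                   paste(best$cluster[best$affiliation == "unassigned"],
                         collapse = ", ")))
  }

  dom_quad <- rep(NA_character_, nrow(best))
  if (!is.null(quadrants)) {
    dom_quad <- vapply(best$cluster, function(cl) {
      genes <- clusters$item[clusters$cluster == cl]
      q <- quadrants$quadrant[quadrants$gene %in% genes]
      if (length(q) == 0) return(NA_character_)
      tq <- sort(table(q), decreasing = TRUE)
      names(tq)[1]
    }, character(1))
  }
  best$dominant_quadrant <- dom_quad
  best$n_genes <- vapply(best$cluster,
                         function(cl) sum(clusters$cluster == cl), integer(1))

  # merge sub-clusters sharing affiliation (and dominant quadrant when known)
  best <- best[order(match(best$cluster, cl_ids)), ]
  key <- paste(best$affiliation,
               ifelse(is.na(best$dominant_quadrant), "", best$dominant_quadrant))
  assigned <- best$affiliation != "unassigned"
  dgn_num <- match(key, unique(key[assigned]))
  best$dgn_id <- ifelse(assigned, paste0("DGN", dgn_num), NA_character_)
  select(best, all_of(c("cluster", "n_genes", "affiliation", "k", "K", "n",
                        "N", "p_value", "adjusted_p", "fold_enrichment",
                        "dominant_quadrant", "dgn_id")))
}
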