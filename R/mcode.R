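# Topological module detection by k-core vertex weighting and greedy seed
# expansion, in the style of molecular-complex detection (MCODE): vertices
# are weighted by the density of the highest k-core of their closed
# neighborhood, then modules grow around high-weight seeds. Expansion here
# admits the seed's neighbors whose weight is within `vwp` of the seed
# weight (one hop); the optional haircut trims singly-connected members,
# which are returned to the seed pool. Modules are vertex-disjoint.

as_dgnet_graph <- function(graph) {
  if (inherits(graph, "igraph")) {
    g <- igraph::simplify(graph, remove.multiple = TRUE, remove.loops = TRUE)
  } else if (inherits(graph, "interactome")) {
    g <- igraph::graph_from_data_frame(graph$edges[, c("gene_a", "gene_b")],
                                       directed = FALSE,
                                       vertices = data.frame(name = graph$members))
    g <- igraph::simplify(g)
  } else if (is.data.frame(graph)) {
    stopifnot(all(c("gene_a", "gene_b") %in% names(graph)))
    g <- igraph::simplify(igraph::graph_from_data_frame(
      graph[, c("gene_a", "gene_b")], directed = FALSE))
  } else {
    abort("graph must be an igraph, interactome, or edge data frame")
  }
  if (is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  }
  g
}

#' k-core vertex weighting
#'
#' For each vertex, takes the induced subgraph on its closed neighborhood
#' (the vertex and its neighbors), finds the highest k-core of that
#' subgraph, and sets `weight = k_max * density(highest k-core)`, where
#' density is `2E / (n (n - 1))`. Members of a clique `K_m` therefore get
#' weight `m - 1`; isolated vertices get 0.
#'
#' @param graph An igraph object, an `interactome`, or an edge tibble with
#'   columns `gene_a`, `gene_b`. Self-loops and multi-edges are removed.
#' @return Tibble with one row per vertex: `gene`, `core` (highest core
#'   number of the closed neighborhood), `core_density`, `weight`, sorted
#'   as in the graph.
#' @export
vertex_weighting <- function(graph) {
  g <- as_dgnet_graph(graph)
  vs <- igraph::V(g)
  res <- purrr::map_dfr(seq_along(vs), function(i) {
    nb <- c(i, as.integer(igraph::neighbors(g, i)))
    sub <- igraph::induced_subgraph(g, nb)
    if (igraph::ecount(sub) == 0) {
      return(tibble(gene = vs$name[i], core = 0L, core_density = 0, weight = 0))
    }
    cores <- igraph::coreness(sub)
    kmax <- max(cores)
    core_sub <- igraph::induced_subgraph(sub, which(cores >= kmax))
    dens <- igraph::edge_density(core_sub)
    tibble(gene = vs$name[i], core = as.integer(kmax),
           core_density = dens, weight = kmax * dens)
  })
  res
}

#' Detect topological modules by greedy seed expansion
#'
#' Seeds are processed in order of decreasing vertex weight (ties by
#' vertex name, so results do not depend on the input row order). From
#' each unused seed, the neighbors whose weight
#' strictly exceeds `(1 - vwp) * weight(seed)` are admitted. With
#' `haircut = TRUE` (default), members connected to the module by a single
#' edge are removed iteratively and returned to the seed pool. With
#' `fluff = TRUE`, unused neighbors of the module whose closed-neighborhood
#' density exceeds `fluff_density` are appended afterwards. Modules have at
#' least 2 genes, induce connected subgraphs, and are vertex-disjoint;
#' they are reported in decreasing score, where
#' `score = density * n_members`.
#'
#' @inheritParams vertex_weighting
#' @param vwp Vertex weight percentage in \[0, 1\] (default 0.2): a
#'   neighbor joins if its weight is within `vwp` of the seed weight.
#' @param haircut Remove singly-connected module members (default TRUE).
#' @param fluff Append dense unused neighbors (default FALSE).
#' @param fluff_density Closed-neighborhood density threshold for fluff
#'   (default 0.2).
#' @param weights Optional precomputed [vertex_weighting()] tibble.
#'
#' @return Tibble with one row per module, in decreasing score:
#'   `module_id`, `n_genes`, `density`, `score`, `seed`, and a `genes`
#'   list-column of member symbols.
#' @export
find_modules <- function(graph, vwp = 0.2, haircut = TRUE, fluff = FALSE,
                         fluff_density = 0.2, weights = NULL) {
  if (length(vwp) != 1 || is.na(vwp) || vwp < 0 || vwp > 1) {
    abort("vwp must be a single value in [0, 1]", class = "dgnet_parameter_error")
  }
  g <- as_dgnet_graph(graph)
  n <- igraph::vcount(g)
  if (n == 0) {
    return(tibble(module_id = character(0), n_genes = integer(0),
                  density = numeric(0), score = numeric(0),
                  seed = character(0), genes = list()))
  }
  w <- weights %||% vertex_weighting(g)
  wv <- setNames(w$weight, w$gene)[igraph::V(g)$name]

  used <- rep(FALSE, n) # vertex already claimed by a module
  seeded <- rep(FALSE, n) # vertex already tried as a seed
  adj <- igraph::adjacent_vertices(g, igraph::V(g))
  modules <- list()

  repeat {
    avail <- which(!used & !seeded)
    if (length(avail) == 0) break
    # ties broken by vertex name so results don't depend on insertion order
    seed <- avail[order(-wv[avail], igraph::V(g)$name[avail])][1]
    seeded[seed] <- TRUE
    if (wv[seed] <= 0) next
    nb <- as.integer(adj[[seed]])
    nb <- nb[!used[nb]]
    admit <- nb[wv[nb] > (1 - vwp) * wv[seed]]
    members <- c(seed, admit)
    if (haircut) {
      repeat {
        if (length(members) < 2) break
        sub <- igraph::induced_subgraph(g, members)
        deg <- igraph::degree(sub)
        drop <- igraph::V(sub)$name[deg < 2]
        if (length(drop) == 0) break
        members <- members[!igraph::V(g)$name[members] %in% drop]
      }
    }
    if (length(members) < 2) next
    if (fluff) {
      border <- setdiff(unique(unlist(lapply(members, function(v)
        as.integer(adj[[v]])))), members)
      border <- border[!used[border]]
      if (length(border) > 0) {
        nd <- vapply(border, function(v) {
          cn <- c(v, as.integer(adj[[v]]))
          sub <- igraph::induced_subgraph(g, cn)
          igraph::edge_density(sub)
        }, numeric(1))
        nd[!is.finite(nd)] <- 0
        members <- c(members, border[nd > fluff_density])
      }
    }
    used[members] <- TRUE
    sub <- igraph::induced_subgraph(g, members)
    dens <- igraph::edge_density(sub)
    modules[[length(modules) + 1]] <- tibble(
      n_genes = length(members), density = dens,
      score = dens * length(members),
      seed = igraph::V(g)$name[seed],
      genes = list(sort(igraph::V(g)$name[members])))
  }

  if (length(modules) == 0) {
    return(tibble(module_id = character(0), n_genes = integer(0),
                  density = numeric(0), score = numeric(0),
                  seed = character(0), genes = list()))
  }
  out <- bind_rows(modules)
  out <- arrange(out, desc(.data$score), .data$seed)
  mutate(out, module_id = sprintf("M%02d", row_number()), .before = 1)
}

#' Annotate topological modules by over-representation
#'
#' Runs [hypergeom_ora()] for each module against a gene-set collection,
#' with Benjamini-Hochberg correction within each module's family of
#' tests.
#'
#' @param modules Tibble from [find_modules()].
#' @param sets A [gene_set_collection()] or named list.
#' @param universe Background gene universe.
#' @return Tibble of enrichment results with a leading `module_id` column.
#' @export
annotate_modules <- function(modules, sets, universe = NULL) {
  stopifnot(nrow(modules) > 0)
  purrr::map_dfr(seq_len(nrow(modules)), function(i) {
    mutate(hypergeom_ora(modules$genes[[i]], sets, universe),
           module_id = modules$module_id[i], .before = 1)
  })
}
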