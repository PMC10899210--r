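# Missing-value-tolerant PCA of the expression matrix via iterative
# truncated SVD imputation, plus quadrant assignment of gene scores and
# quadrant-wise gene-set enrichment.

#' Scale rows (or columns) to zero mean and unit variance
#'
#' Centers and scales each vector over its non-missing entries using the
#' sample standard deviation. Zero-variance vectors are an error that
#' names the offending genes.
#'
#' @param matrix Numeric matrix, possibly with missing cells.
#' @param margin `"rows"` (gene-wise, default) or `"columns"`.
#' @return Matrix of the same shape (class and attributes preserved).
#' @export
scale_unit_variance <- function(matrix, margin = c("rows", "columns")) {
  margin <- match.arg(margin)
  m <- unclass(matrix)
  flip <- margin == "columns"
  if (flip) m <- t(m)
  nobs <- rowSums(!is.na(m))
  if (any(nobs < 2)) {
    abort(sprintf("rows with fewer than 2 non-missing values: %s",
                  paste(head(rownames(m)[nobs < 2], 5), collapse = ", ")))
  }
  mu <- rowMeans(m, na.rm = TRUE)
  s <- apply(m, 1, sd, na.rm = TRUE)
  if (any(s == 0)) {
    abort(sprintf("zero-variance rows cannot be scaled: %s",
                  paste(head(rownames(m)[s == 0], 5), collapse = ", ")),
          class = "dgnet_validation_error")
  }
  out <- (m - mu) / s
  if (flip) out <- t(out)
  attributes(out)[c("coords", "dropped_genes", "class")] <-
    attributes(matrix)[c("coords", "dropped_genes", "class")]
  out
}

#' Principal components by truncated SVD with missing-value imputation
#'
#' Missing cells are initialised with column means, then the scheme
#' alternates a rank-`n_components` SVD reconstruction with refilling of
#' the missing cells until the largest absolute change in any imputed cell
#' drops below `tol` or `max_iter` is reached. On a complete matrix this is
#' exactly one truncated SVD. The procedure is deterministic. Component
#' signs are oriented so that the loading of largest absolute magnitude in
#' each component is positive; the applied flips are recorded so an
#' external orientation can be matched post hoc.
#'
#' @param matrix Numeric matrix (genes x coordinates), typically scaled
#'   with [scale_unit_variance()].
#' @param n_components Number of components to extract (<= min(dim)).
#' @param tol Convergence tolerance on imputed cells (default 1e-6).
#' @param max_iter Maximum number of impute/SVD iterations (default 500).
#'
#' @return An object of class `dgn_pca`: `scores` (genes x components),
#'   `loadings`, `singular_values`, `variance_explained` (fraction of total
#'   variance per component), `n_iterations`, `converged`, `sign_flips`.
#'   Non-convergence yields a warning, not an error.
#' @export
svd_impute <- function(matrix, n_components = 2, tol = 1e-6, max_iter = 500) {
  m <- unclass(matrix)
  if (n_components > min(dim(m))) {
    abort("n_components exceeds matrix dimensions", class = "dgnet_parameter_error")
  }
  miss <- is.na(m)
  filled <- m
  if (any(miss)) {
    colmu <- colMeans(m, na.rm = TRUE)
    colmu[is.nan(colmu)] <- 0
    filled[miss] <- colmu[col(m)[miss]]
  }
  n_iter <- 0L
  converged <- TRUE
  if (any(miss)) {
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      sv <- svd(filled, nu = n_components, nv = n_components)
      recon <- sv$u %*% (sv$d[seq_len(n_components)] * t(sv$v))
      delta <- max(abs(recon[miss] - filled[miss]))
      filled[miss] <- recon[miss]
      n_iter <- it
      if (delta < tol) {
        converged <- TRUE
        break
      }
    }
    if (!converged) {
      warn(sprintf("svd_impute did not converge in %d iterations", max_iter))
    }
  }
  sv <- svd(filled)
  d <- sv$d
  u <- sv$u[, seq_len(n_components), drop = FALSE]
  v <- sv$v[, seq_len(n_components), drop = FALSE]
  # sign convention: largest-|loading| entry of each component positive
  flips <- vapply(seq_len(n_components), function(j) {
    sign(v[which.max(abs(v[, j])), j])
  }, numeric(1))
  flips[flips == 0] <- 1
  u <- sweep(u, 2, flips, `*`)
  v <- sweep(v, 2, flips, `*`)
  scores <- sweep(u, 2, d[seq_len(n_components)], `*`)
  dimnames(scores) <- list(rownames(m),
                           paste0("PC", seq_len(n_components)))
  dimnames(v) <- list(colnames(m), colnames(scores))
  structure(list(scores = scores, loadings = v,
                 singular_values = d[seq_len(n_components)],
                 variance_explained = d[seq_len(n_components)]^2 / sum(d^2),
                 n_iterations = n_iter, converged = converged,
                 sign_flips = flips),
            class = "dgn_pca")
}

#' @export
print.dgn_pca <- function(x, ...) {
  cat(sprintf("<dgn_pca: %d genes, %d components (%s of variance), %s after %d iteration(s)>\n",
              nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * x$variance_explained), collapse = " + "),
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  invisible(x)
}

#' @method tidy dgn_pca
#' @export
tidy.dgn_pca <- function(x, ...) {
  out <- as_tibble(x$scores)
  mutate(out, gene = rownames(x$scores), .before = 1)
}

#' @method glance dgn_pca
#' @export
glance.dgn_pca <- function(x, ...) {
  tibble(n_components = ncol(x$scores),
         pc1_variance = x$variance_explained[1],
         pc2_variance = if (length(x$variance_explained) > 1)
           x$variance_explained[2] else NA_real_,
         n_iterations = x$n_iterations, converged = x$converged)
}

#' Assign genes to PCA quadrants
#'
#' Quadrants follow the usual orientation on the (PC1, PC2) plane:
#' I = (+, +), II = (-, +), III = (-, -), IV = (+, -). Exact zero scores
#' are resolved to the positive side and counted in a message.
#'
#' @param pca A `dgn_pca` with at least 2 components.
#' @return Tibble with columns `gene`, `pc1`, `pc2`, `quadrant` (factor
#'   with levels I-IV).
#' @export
assign_quadrants <- function(pca) {
  stopifnot(inherits(pca, "dgn_pca"), ncol(pca$scores) >= 2)
  pc1 <- pca$scores[, 1]
  pc2 <- pca$scores[, 2]
  nzero <- sum(pc1 == 0) + sum(pc2 == 0)
  if (nzero > 0) {
    inform(sprintf("assign_quadrants: %d exact-zero score(s) resolved to the positive side", nzero))
  }
  pos1 <- pc1 >= 0
  pos2 <- pc2 >= 0
  quad <- ifelse(pos1 & pos2, "I",
                 ifelse(!pos1 & pos2, "II",
                        ifelse(!pos1 & !pos2, "III", "IV")))
  tibble(gene = rownames(pca$scores) %||% as.character(seq_along(pc1)),
         pc1 = unname(pc1), pc2 = unname(pc2),
         quadrant = factor(quad, levels = c("I", "II", "III", "IV")))
}

#' Quadrant-wise gene-set enrichment
#'
#' For each quadrant — optionally intersected with each gene cluster —
#' tests every gene set for over-representation (hypergeometric upper
#' tail), with Benjamini-Hochberg correction across the whole family of
#' tests. Intersection counts and two percentages are reported:
#' `percent_of_query` (share of the quadrant query covered by the set, as
#' in "36.5% of quadrant I genes were unique SZ interactome genes") and
#' `percent_of_set` (share of the set falling in the quadrant; sums to
#' 100 over quadrants when the set lies in the assigned universe).
#'
#' @param assignment Tibble from [assign_quadrants()].
#' @param gene_sets A [gene_set_collection()] or named list.
#' @param universe Background gene universe.
#' @param clusters Optional tibble from [cut_tree()]; when given, queries
#'   are quadrant-by-cluster intersections.
#'
#' @return Tibble with one row per (quadrant\[, cluster\], set):
#'   `quadrant`, `cluster`, `set_id`, `k`, `K`, `n`, `N`, `percent`,
#'   `fold_enrichment`, `p_value`, `adjusted_p`.
#' @export
quadrant_enrichment <- function(assignment, gene_sets, universe,
                                clusters = NULL) {
  if (inherits(gene_sets, "gene_set_collection")) gene_sets <- gene_sets$sets
  universe <- unique(as.character(universe))
  N <- length(universe)

  queries <- list()
  for (q in levels(assignment$quadrant)) {
    qgenes <- assignment$gene[assignment$quadrant == q]
    if (is.null(clusters)) {
      queries[[length(queries) + 1]] <-
        list(quadrant = q, cluster = NA_character_, genes = qgenes)
    } else {
      for (cl in unique(clusters$cluster)) {
        g <- intersect(qgenes, clusters$item[clusters$cluster == cl])
        if (length(g) == 0) {
          inform(sprintf("quadrant_enrichment: empty intersection %s x %s skipped", q, cl))
          next
        }
        queries[[length(queries) + 1]] <-
          list(quadrant = q, cluster = cl, genes = g)
      }
    }
  }

  res <- purrr::map_dfr(queries, function(qu) {
    genes <- intersect(qu$genes, universe)
    purrr::map_dfr(names(gene_sets), function(sid) {
      s <- intersect(gene_sets[[sid]], universe)
      k <- length(intersect(genes, s))
      K <- length(s); nn <- length(genes)
      lp <- if (k == 0) 0 else phyper(k - 1, K, N - K, nn,
                                      lower.tail = FALSE, log.p = TRUE)
      tibble(quadrant = qu$quadrant, cluster = qu$cluster, set_id = sid,
             k = k, K = K, n = nn, N = N,
             percent_of_query = if (nn > 0) 100 * k / nn else NA_real_,
             percent_of_set = if (K > 0) 100 * k / K else NA_real_,
             fold_enrichment = if (K * nn > 0) k * N / (K * nn) else NA_real_,
             p_value = exp(lp))
    })
  })
  res$adjusted_p <- bh_adjust(res$p_value)
  res
}
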