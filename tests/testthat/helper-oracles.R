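# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: exhaustive enumeration for the hypergeometric
# tail, a quadratic-time direct step-up rule for BH, and a from-scratch
# O(n^3) recomputation for UPGMA.

`%||%` <- function(a, b) if (is.null(a)) b else a

# P(X >= k) for X ~ Hypergeometric(N, K, n), by summing the exact pmf.
enum_hyper_tail <- function(N, K, n, k) {
  if (k <= 0) return(1)
  i <- k:min(K, n)
  i <- i[n - i <= N - K]
  if (length(i) == 0) return(0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Direct quadratic-time BH: adjusted_(i) = min_{j >= i} p_(j) * m / j.
bh_direct <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj_sorted <- vapply(seq_len(m), function(i) {
    min(vapply(i:m, function(j) ps[j] * m / j, numeric(1)), 1)
  }, numeric(1))
  out <- numeric(m)
  out[ord] <- adj_sorted
  out
}

# Naive UPGMA: cluster memberships kept explicitly; every inter-cluster
# distance recomputed from the original matrix at every step.
naive_upgma <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  ids <- -seq_len(n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    m <- length(clusters)
    best <- Inf; bi <- 0; bj <- 0
    for (j in 2:m) {
      for (i in 1:(j - 1)) {
        avg <- mean(d[clusters[[i]], clusters[[j]], drop = FALSE])
        if (avg < best) { best <- avg; bi <- i; bj <- j }
      }
    }
    pair <- c(ids[bi], ids[bj])
    merge[step, ] <- pair[order(pair >= 0, abs(pair))]
    height[step] <- best
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    ids[bi] <- step
    clusters[[bj]] <- NULL
    ids <- ids[-bj]
  }
  list(merge = merge, height = height)
}

# Symmetric random distance matrix with distinct off-diagonal entries.
random_tie_free_dist <- function(n, labels = NULL) {
  repeat {
    v <- stats::runif(n * (n - 1) / 2)
    if (!anyDuplicated(v)) break
  }
  d <- matrix(0, n, n)
  d[lower.tri(d)] <- v
  d <- d + t(d)
  rownames(d) <- colnames(d) <- labels %||% paste0("t", seq_len(n))
  stats::as.dist(d)
}
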