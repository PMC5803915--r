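# Independent oracles for graph metrics, statistics and correlations.
# They deliberately take different computational routes from the package:
# shortest paths through igraph, efficiencies by materialised subgraphs,
# clustering by explicit triangle enumeration, Spearman by rank-then-Pearson,
# and Kruskal-Wallis by a from-scratch rank-sum formula.

oracle_distances <- function(w) {
  n <- nrow(w)
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (igraph::ecount(g) == 0) {
    d <- matrix(Inf, n, n)
    diag(d) <- 0
    return(d)
  }
  igraph::distances(g, weights = 1 / igraph::E(g)$weight)
}

oracle_global_efficiency <- function(w) {
  n <- nrow(w)
  if (n < 2) stop("need >= 2 nodes")
  d <- oracle_distances(w)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

oracle_nodal_efficiency <- function(w) {
  n <- nrow(w)
  vapply(seq_len(n), function(i) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2) return(0)
    oracle_global_efficiency(w[nb, nb, drop = FALSE])
  }, numeric(1))
}

# binary and Onnela weighted clustering by explicit triple loops
oracle_clustering <- function(w) {
  n <- nrow(w)
  binary <- all(w %in% c(0, 1))
  wh <- if (binary || max(w) == 0) w else (w / max(w))^(1 / 3)
  out <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(w[i, ] > 0)
    if (k < 2) next
    acc <- 0
    for (j in seq_len(n)) {
      for (h in seq_len(n)) {
        if (j != i && h != i && j != h) {
          acc <- acc + wh[i, j] * wh[i, h] * wh[j, h]
        }
      }
    }
    out[i] <- acc / (k * (k - 1))
  }
  out
}

oracle_spearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Kruskal-Wallis H with tie correction from the textbook rank-sum formula
oracle_kw_h <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  r <- rank(pooled)
  ra <- sum(r[seq_along(a)])
  rb <- sum(r[-seq_along(a)])
  h <- 12 / (n * (n + 1)) *
    (ra^2 / length(a) + rb^2 / length(b)) - 3 * (n + 1)
  ties <- table(pooled)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# exhaustive permutation p-value for the two-group H statistic
oracle_kw_perm_p <- function(a, b) {
  pooled <- c(a, b)
  h_obs <- oracle_kw_h(a, b)
  combos <- utils::combn(length(pooled), length(a))
  h_all <- apply(combos, 2, function(idx) {
    oracle_kw_h(pooled[idx], pooled[-idx])
  })
  mean(h_all >= h_obs - 1e-12)
}

random_binary_graph <- function(n, p = 0.4) {
  w <- matrix(0, n, n)
  w[upper.tri(w)] <- rbinom(n * (n - 1) / 2, 1, p)
  w + t(w)
}

random_weighted_graph <- function(n, p = 0.4) {
  w <- matrix(0, n, n)
  e <- rbinom(n * (n - 1) / 2, 1, p) * runif(n * (n - 1) / 2, 0.1, 3)
  w[upper.tri(w)] <- e
  w + t(w)
}

# all undirected graphs on n nodes, as adjacency matrices (2^(n(n-1)/2))
enumerate_graphs <- function(n) {
  m <- n * (n - 1) / 2
  lapply(seq_len(2^m) - 1L, function(code) {
    bits <- as.integer(intToBits(code))[seq_len(m)]
    w <- matrix(0, n, n)
    w[upper.tri(w)] <- bits
    w + t(w)
  })
}
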