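#' All-pairs shortest path lengths of a connectome
#'
#' Edge lengths are the inverse of the connection weight (so strong
#' connections are short); on a binary connectome every hop has length 1.
#' Distances between disconnected nodes are `Inf`, which downstream
#' efficiency metrics map to a contribution of 0.
#'
#' @param conn A `connectome`, or a symmetric non-negative weight matrix.
#' @return An `N x N` matrix of distances with zero diagonal.
#' @export
shortest_path_matrix <- function(conn) {
  w <- connectome_weights(conn)
  n <- nrow(w)
  d <- 1 / w
  d[w == 0] <- Inf
  diag(d) <- 0
  # Floyd-Warshall, vectorised over one index
  for (k in seq_len(n)) {
    dk <- outer(d[, k], d[k, ], "+")
    upd <- dk < d
    if (any(upd)) d[upd] <- dk[upd]
  }
  dimnames(d) <- dimnames(w)
  d
}

connectome_weights <- function(conn) {
  if (inherits(conn, "connectome")) return(conn$weights)
  w <- as.matrix(conn)
  if (nrow(w) != ncol(w)) abort("weight matrix must be square")
  if (any(w < 0)) abort("weights must be non-negative")
  if (max(abs(w - t(w))) > 1e-12) abort("weight matrix must be symmetric")
  diag(w) <- 0
  w
}

#' Global efficiency of a network
#'
#' The mean over ordered node pairs of the inverse shortest path length,
#' with unreachable pairs contributing 0. It is 1 on a binary complete graph
#' and 0 on an empty one; high values mean short routes between regions
#' (network integration).
#'
#' @param conn A `connectome` or weight matrix with at least 2 nodes.
#' @return Scalar efficiency, non-negative (in \[0, 1\] for binary graphs).
#' @export
global_efficiency <- function(conn) {
  w <- connectome_weights(conn)
  if (nrow(w) < 2) abort("global efficiency needs at least 2 nodes")
  d <- shortest_path_matrix(w)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv) / (nrow(w) * (nrow(w) - 1))
}

#' Nodal (local) efficiency of each node
#'
#' The efficiency of the subnetwork associated with a node: the global
#' efficiency of the subgraph induced by the node's neighbours, the node
#' itself excluded. Nodes with fewer than two neighbours score 0. A
#' closeness-type alternative (`definition = "closeness"`: mean inverse
#' shortest-path length from the node to every other node) is provided for
#' comparison with studies that use that reading, but the subgraph definition
#' is the default.
#'
#' @param conn A `connectome` or weight matrix.
#' @param nodes Integer vector of 1-based node positions (default all).
#' @param definition `"subgraph"` (default) or `"closeness"`.
#' @return Numeric vector of efficiencies, one per requested node.
#' @export
nodal_efficiency <- function(conn, nodes = NULL,
                             definition = c("subgraph", "closeness")) {
  definition <- match.arg(definition)
  w <- connectome_weights(conn)
  n <- nrow(w)
  nodes <- check_nodes(nodes, n)
  if (definition == "closeness") {
    d <- shortest_path_matrix(w)
    inv <- 1 / d
    inv[is.infinite(d)] <- 0
    diag(inv) <- 0
    return(unname(rowSums(inv)[nodes]) / (n - 1))
  }
  vapply(nodes, function(i) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2) return(0)
    global_efficiency(w[nb, nb, drop = FALSE])
  }, numeric(1))
}

check_nodes <- function(nodes, n) {
  if (is.null(nodes)) return(seq_len(n))
  if (any(!nodes %in% seq_len(n))) abort("invalid node index")
  nodes
}

#' Clustering coefficient of each node
#'
#' On a binary network: the fraction of a node's neighbour pairs that are
#' themselves connected (closed triangles over `k(k-1)/2`). On a weighted
#' network the Onnela geometric-mean formula is used: weights are normalised
#' by the network maximum and each triangle contributes the cube root of its
#' weight product, `C_i = (sum over triangles)/(k_i (k_i - 1))`, which
#' reduces to the binary value when all weights are equal. Nodes with degree
#' below 2 score 0.
#'
#' @inheritParams nodal_efficiency
#' @return Numeric vector of clustering coefficients.
#' @export
clustering_coefficient <- function(conn, nodes = NULL) {
  w <- connectome_weights(conn)
  n <- nrow(w)
  nodes <- check_nodes(nodes, n)
  k <- rowSums(w > 0)
  if (max(w) == 0) return(rep(0, length(nodes)))
  binary <- all(w %in% c(0, 1))
  wh <- if (binary) w else (w / max(w))^(1 / 3)
  tri <- diag(wh %*% wh %*% wh)   # 2x the triangle intensity around each node
  cc <- ifelse(k < 2, 0, tri / (k * (k - 1)))
  unname(cc[nodes])
}

#' Nodal and global graph metrics of a connectome
#'
#' Nodal metrics are degree (count of connections), strength (sum of
#' connection weights), nodal efficiency ([nodal_efficiency()]) and
#' clustering coefficient ([clustering_coefficient()]). Global degree,
#' strength, local efficiency and average clustering are the arithmetic
#' means of the nodal values over all nodes; global efficiency is computed
#' once on the full graph.
#'
#' @param conn A `connectome`.
#' @param definition Nodal-efficiency definition, see [nodal_efficiency()].
#' @return A list with tibbles `nodal` (one row per node) and `global` (one
#'   row).
#' @examples
#' tab <- read_region_table(example_region_table_path())
#' sl <- tibble::tibble(start_index = c(1, 1, 2), end_index = c(2, 3, 3),
#'                      length_mm = 5, mean_fa = 0.5)
#' summarize_connectome(build_structural_connectome(sl, tab, "binary"))$global
#' @export
summarize_connectome <- function(conn, definition = "subgraph") {
  stopifnot(inherits(conn, "connectome"))
  w <- conn$weights
  nodal <- tibble(
    node_label = conn$nodes$label,
    degree = as.integer(rowSums(w > 0)),
    strength = unname(rowSums(w)),
    nodal_efficiency = nodal_efficiency(w, definition = definition),
    clustering = clustering_coefficient(w)
  )
  global <- tibble(
    avg_degree = mean(nodal$degree),
    avg_strength = mean(nodal$strength),
    global_efficiency = global_efficiency(w),
    local_efficiency = mean(nodal$nodal_efficiency),
    avg_clustering = mean(nodal$clustering)
  )
  list(nodal = nodal, global = global)
}

#' Tidy metric table for one or many connectomes
#'
#' Emits the long format used by the statistics stage and the CSV outputs:
#' one row per (subject, connectome kind, scope, node, metric).
#'
#' @param conns A `connectome` or a list of them.
#' @param ... Passed to [summarize_connectome()].
#' @return A tibble with columns `subject_id`, `connectome_kind`, `scope`
#'   (`"global"` or `"node"`), `node_label` (`NA` for global rows),
#'   `metric_name`, `value`.
#' @export
connectome_metrics <- function(conns, ...) {
  if (inherits(conns, "connectome")) conns <- list(conns)
  purrr::map_dfr(conns, function(conn) {
    s <- summarize_connectome(conn, ...)
    nodal_long <- tidyr::pivot_longer(
      s$nodal, -"node_label",
      names_to = "metric_name", values_to = "value"
    )
    global_long <- tidyr::pivot_longer(
      s$global, dplyr::everything(),
      names_to = "metric_name", values_to = "value"
    )
    bind_rows(
      mutate(global_long, scope = "global", node_label = NA_character_),
      mutate(nodal_long, scope = "node")
    ) |>
      mutate(
        subject_id = conn$subject_id %||% NA_character_,
        connectome_kind = conn$kind
      ) |>
      select("subject_id", "connectome_kind", "scope", "node_label",
             "metric_name", "value")
  })
}
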