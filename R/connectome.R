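#' Construct a connectome object
#'
#' A connectome is a symmetric, zero-diagonal, non-negative adjacency matrix
#' over a declared node set, together with the weighting kind. Binary kinds
#' (`binary`, `func_binary`) may contain only 0/1.
#'
#' @param weights N x N numeric matrix.
#' @param nodes Node tibble as returned by [structural_nodes()] or
#'   [functional_nodes()].
#' @param kind One of `"binary"`, `"fa_weighted"`, `"fd_weighted"`,
#'   `"func_weighted"`, `"func_binary"`.
#' @param subject_id Optional subject identifier carried through to outputs.
#' @return An object of class `connectome`.
#' @export
new_connectome <- function(weights, nodes, kind, subject_id = NULL) {
  kinds <- c("binary", "fa_weighted", "fd_weighted", "func_weighted",
             "func_binary")
  if (!is.character(kind) || length(kind) != 1 || !kind %in% kinds) {
    abort(paste0("unknown connectome kind; must be one of: ",
                 paste(kinds, collapse = ", ")))
  }
  weights <- as.matrix(weights)
  n <- nrow(nodes)
  if (!is.numeric(weights) || nrow(weights) != n || ncol(weights) != n) {
    abort("weights must be a numeric N x N matrix matching the node set")
  }
  if (any(!is.finite(weights))) abort("weights must be finite")
  if (any(weights < 0)) abort("weights must be non-negative")
  if (max(abs(weights - t(weights))) > 1e-12) {
    abort("weights must be symmetric")
  }
  weights <- (weights + t(weights)) / 2
  if (any(diag(weights) != 0)) abort("diagonal must be zero")
  if (kind %in% c("binary", "func_binary") && !all(weights %in% c(0, 1))) {
    abort("binary connectome entries must be 0 or 1")
  }
  dimnames(weights) <- list(nodes$label, nodes$label)
  structure(
    list(weights = weights, nodes = nodes, kind = kind,
         subject_id = subject_id),
    class = "connectome"
  )
}

#' @export
print.connectome <- function(x, ...) {
  n <- nrow(x$weights)
  m <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("<connectome> kind=%s, %d nodes, %d edges, density %.3f\n",
              x$kind, n, m, m / choose(n, 2)))
  if (!is.null(x$subject_id)) cat("subject:", x$subject_id, "\n")
  invisible(x)
}

#' Tidy a connectome into an edge list
#'
#' @param x A `connectome`.
#' @param ... Unused.
#' @return A tibble with one row per present edge: `from`, `to` (node
#'   labels), `from_id`, `to_id` (0-based), `weight`, `kind`.
#' @export
tidy.connectome <- function(x, ...) {
  w <- x$weights
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  tibble(
    from = x$nodes$label[idx[, 1]],
    to = x$nodes$label[idx[, 2]],
    from_id = x$nodes$node_id[idx[, 1]],
    to_id = x$nodes$node_id[idx[, 2]],
    weight = w[idx],
    kind = x$kind
  )
}

#' One-row summary of a connectome
#'
#' @param x A `connectome`.
#' @param ... Unused.
#' @return A tibble with node count, edge count, density, total weight, kind.
#' @export
glance.connectome <- function(x, ...) {
  w <- x$weights
  up <- w[upper.tri(w)]
  tibble(
    nodes = nrow(w),
    edges = sum(up > 0),
    density = sum(up > 0) / length(up),
    total_weight = sum(up),
    kind = x$kind
  )
}

#' Heatmap of a connectome adjacency matrix
#'
#' @param object A `connectome`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.connectome <- function(object, ...) {
  w <- object$weights
  df <- tidyr::expand_grid(
    row = factor(rownames(w), levels = rev(rownames(w))),
    col = factor(colnames(w), levels = colnames(w))
  )
  # expand_grid is row-major over `row` (reversed for display); match it
  df$weight <- as.vector(t(w[rev(seq_len(nrow(w))), , drop = FALSE]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$weight)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = object$kind,
                  title = sprintf("%s connectome", object$kind)) +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Write / read a connectome as a labelled CSV matrix with a JSON sidecar
#'
#' The matrix is written with node labels as header row and first column;
#' the sidecar `<path>.json` records `kind`, `node_count` and `subject_id`.
#'
#' @param conn A `connectome`.
#' @param path Output CSV path.
#' @return `write_connectome()` returns `path` invisibly; `read_connectome()`
#'   returns a `connectome` (node set reconstructed from `nodes`).
#' @param nodes Node tibble matching the stored matrix labels.
#' @export
write_connectome <- function(conn, path) {
  df <- as.data.frame(conn$weights)
  df <- cbind(label = rownames(conn$weights), df)
  readr::write_csv(as_tibble(df), path, progress = FALSE)
  jsonlite::write_json(
    list(kind = conn$kind, node_count = nrow(conn$weights),
         subject_id = conn$subject_id),
    paste0(path, ".json"), auto_unbox = TRUE, null = "null"
  )
  invisible(path)
}

#' @rdname write_connectome
#' @export
read_connectome <- function(path, nodes) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  w <- as.matrix(df[, -1])
  if (!identical(df$label, nodes$label)) {
    abort("stored node labels do not match the supplied node set")
  }
  new_connectome(w, nodes, meta$kind, subject_id = meta$subject_id)
}

#' Binarize a weighted connectome
#'
#' Sets every strictly positive weight to 1. The binary kind mirrors the
#' weighted kind it came from (`func_weighted` maps to `func_binary`,
#' structural kinds to `binary`).
#'
#' @param conn A `connectome`.
#' @return A binary `connectome`.
#' @export
binarize <- function(conn) {
  kind <- if (conn$kind %in% c("func_weighted", "func_binary")) {
    "func_binary"
  } else {
    "binary"
  }
  new_connectome((conn$weights > 0) * 1, conn$nodes, kind,
                 subject_id = conn$subject_id)
}
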