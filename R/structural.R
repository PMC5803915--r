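#' Fiber density of a connection
#'
#' The fiber density (FD) between regions I and J is the sum of inverse
#' streamline lengths over all streamlines joining the pair, normalised by the
#' product of the two region volumes:
#'
#' \deqn{FD = \frac{1}{V_i V_j} \sum_{s \in S_{ij}} \frac{1}{l(s)}}
#'
#' Longer streamlines contribute less (they traverse more tissue per
#' connection) and the volume normalisation removes the trivial dependence of
#' streamline counts on region size. An empty streamline set has FD 0.
#'
#' @param lengths_mm Numeric vector of streamline lengths in mm (may be
#'   empty).
#' @param vol_i,vol_j Region volumes in cubic millimetres (> 0).
#' @return Non-negative scalar, in units of mm^-1 per mm^6.
#' @examples
#' fiber_density(c(1, 2, 4), vol_i = 2, vol_j = 1)  # 0.875
#' @export
fiber_density <- function(lengths_mm, vol_i, vol_j) {
  if (!is.finite(vol_i) || !is.finite(vol_j) || vol_i <= 0 || vol_j <= 0) {
    abort("region volumes must be positive")
  }
  if (length(lengths_mm) == 0) return(0)
  if (any(!is.finite(lengths_mm)) || any(lengths_mm <= 0)) {
    abort("streamline lengths must be positive")
  }
  sum(1 / lengths_mm) / (vol_i * vol_j)
}

#' Mean fractional anisotropy over the streamlines of a connection
#'
#' @param fa Numeric vector of per-streamline mean FA values in \[0, 1\];
#'   must be non-empty (an edge only exists where at least one streamline
#'   joins the pair).
#' @return The unweighted arithmetic mean, in \[0, 1\].
#' @export
mean_edge_fa <- function(fa) {
  if (length(fa) == 0) abort("no streamlines: edge does not exist")
  if (any(!is.finite(fa)) || any(fa < 0) || any(fa > 1)) {
    abort("FA values must lie in [0, 1]")
  }
  mean(fa)
}

#' Validate a streamline record table
#'
#' @param streamlines Data frame with columns `start_index`, `end_index`
#'   (1-based structural region indexes), `length_mm`, `mean_fa`, and
#'   optionally `subject_id`.
#' @param n_nodes Number of structural nodes; endpoint indexes must lie in
#'   `1..n_nodes`.
#' @return The validated tibble.
#' @export
validate_streamlines <- function(streamlines, n_nodes) {
  required <- c("start_index", "end_index", "length_mm", "mean_fa")
  missing <- setdiff(required, names(streamlines))
  if (length(missing) > 0) {
    abort(paste0("streamline table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  streamlines <- as_tibble(streamlines)
  for (col in c("start_index", "end_index")) {
    v <- streamlines[[col]]
    bad <- !is.finite(v) | v < 1 | v > n_nodes | v != round(v)
    if (any(bad)) {
      abort(paste0("streamline endpoint outside the 1..", n_nodes,
                   " node range in row(s) ",
                   paste(head(which(bad), 5), collapse = ", ")))
    }
  }
  bad_len <- !is.finite(streamlines$length_mm) | streamlines$length_mm <= 0
  if (any(bad_len)) {
    abort(paste0("non-positive streamline length in row(s) ",
                 paste(head(which(bad_len), 5), collapse = ", ")))
  }
  bad_fa <- !is.finite(streamlines$mean_fa) | streamlines$mean_fa < 0 |
    streamlines$mean_fa > 1
  if (any(bad_fa)) {
    abort(paste0("streamline FA outside [0, 1] in row(s) ",
                 paste(head(which(bad_fa), 5), collapse = ", ")))
  }
  streamlines
}

#' Build a structural connectome from streamline records
#'
#' Two regions are connected if at least one streamline joins them, in either
#' orientation: tractography streamlines carry no anatomical direction, so the
#' unordered endpoint pair defines the edge and the matrix is symmetric by
#' construction. Streamlines starting and ending in the same region are
#' dropped (graph metrics assume a zero diagonal).
#'
#' @param streamlines Streamline table (see [validate_streamlines()]); its
#'   endpoint indexes are the table's 1-based structural indexes.
#' @param region_table A validated region table; defines the node set and the
#'   volumes used by the fiber-density weighting.
#' @param kind `"binary"` (0/1 presence), `"fa_weighted"` (mean FA over the
#'   pair's streamlines) or `"fd_weighted"` (fiber density, [fiber_density()]).
#' @param subject_id Optional subject identifier.
#' @return A `connectome` over [structural_nodes()] of the table.
#' @examples
#' tab <- read_region_table(example_region_table_path())
#' sl <- tibble::tibble(start_index = 1, end_index = 2,
#'                      length_mm = 2, mean_fa = 0.4)
#' conn <- build_structural_connectome(sl, tab, kind = "binary")
#' conn$weights[1, 2]  # 1
#' @export
build_structural_connectome <- function(streamlines, region_table,
                                        kind = c("binary", "fa_weighted",
                                                 "fd_weighted"),
                                        subject_id = NULL) {
  kind <- match.arg(kind)
  region_table <- validate_region_table(region_table)
  nodes <- structural_nodes(region_table)
  n <- nrow(nodes)
  streamlines <- validate_streamlines(streamlines, n)

  # region volume in node order (source_index is the 1-based file index)
  vol <- region_table$volume_mm3[match(nodes$source_index,
                                       region_table$structural_index)]

  w <- matrix(0, n, n)
  keep <- streamlines$start_index != streamlines$end_index
  sl <- streamlines[keep, ]
  if (nrow(sl) > 0) {
    i <- pmin(sl$start_index, sl$end_index)
    j <- pmax(sl$start_index, sl$end_index)
    pair <- (i - 1L) * n + j  # unordered-pair key
    if (kind == "binary") {
      agg <- tapply(rep(1, nrow(sl)), pair, max)
    } else if (kind == "fa_weighted") {
      agg <- tapply(sl$mean_fa, pair, mean)
    } else {
      inv_len <- tapply(1 / sl$length_mm, pair, sum)
      keys <- as.integer(names(inv_len))
      ii <- (keys - 1L) %/% n + 1L
      jj <- (keys - 1L) %% n + 1L
      agg <- inv_len / (vol[ii] * vol[jj])
    }
    keys <- as.integer(names(agg))
    ii <- (keys - 1L) %/% n + 1L
    jj <- (keys - 1L) %% n + 1L
    w[cbind(ii, jj)] <- as.numeric(agg)
    w[cbind(jj, ii)] <- as.numeric(agg)
  }
  new_connectome(w, nodes, kind, subject_id = subject_id)
}

#' Read / write streamline record tables
#'
#' TSV with columns `subject_id`, `start_index`, `end_index` (1-based
#' structural region indexes), `length_mm`, `mean_fa`.
#'
#' @param path File path.
#' @param streamlines Streamline tibble.
#' @return A tibble (`read_streamlines`) or `path` invisibly.
#' @export
read_streamlines <- function(path) {
  if (!file.exists(path)) abort(paste0("streamline file not found: ", path))
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    subject_id = readr::col_character(),
                    start_index = readr::col_integer(),
                    end_index = readr::col_integer(),
                    length_mm = readr::col_double(),
                    mean_fa = readr::col_double()
                  ))
}

#' @rdname read_streamlines
#' @export
write_streamlines <- function(streamlines, path) {
  readr::write_tsv(streamlines, path, progress = FALSE)
  invisible(path)
}
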