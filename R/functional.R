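#' Create a regional time-series object
#'
#' Holds an `N x T` matrix of regional BOLD signals (rows = regions in
#' functional node order, columns = time points), the sampling interval and a
#' provenance list of applied processing steps.
#'
#' @param data Numeric matrix, regions x time.
#' @param tr_seconds Sampling interval (repetition time) in seconds.
#' @param band_hz Length-2 numeric `(low, high)` if a band-pass has been
#'   applied, else `NULL`.
#' @param provenance Character vector of processing steps already applied.
#' @param subject_id Optional subject identifier.
#' @return An object of class `regional_ts`.
#' @export
regional_ts <- function(data, tr_seconds = 2, band_hz = NULL,
                        provenance = character(), subject_id = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data) || ncol(data) < 2) {
    abort("time series must be a numeric matrix with at least 2 time points")
  }
  if (any(!is.finite(data))) abort("time series contains missing values")
  if (!is.numeric(tr_seconds) || tr_seconds <= 0) {
    abort("tr_seconds must be positive")
  }
  structure(
    list(data = data, tr_seconds = tr_seconds, band_hz = band_hz,
         provenance = provenance, subject_id = subject_id),
    class = "regional_ts"
  )
}

#' @export
print.regional_ts <- function(x, ...) {
  cat(sprintf("<regional_ts> %d regions x %d samples, TR = %gs\n",
              nrow(x$data), ncol(x$data), x$tr_seconds))
  if (length(x$provenance)) {
    cat("processing:", paste(x$provenance, collapse = " -> "), "\n")
  }
  invisible(x)
}

detrend_rows <- function(m) {
  t_idx <- seq_len(ncol(m))
  d <- cbind(1, t_idx - mean(t_idx))
  # residuals of each row regressed on [1, t], computed jointly
  beta <- solve(crossprod(d), crossprod(d, t(m)))
  m - t(d %*% beta)
}

bandpass_rows <- function(m, band_hz, tr) {
  tt <- ncol(m)
  freqs <- (seq_len(tt) - 1) / (tt * tr)
  freqs <- pmin(freqs, 1 / tr - freqs)  # fold to [0, Nyquist]
  keep <- freqs >= band_hz[1] & freqs <= band_hz[2]
  ft <- t(apply(m, 1, fft))
  ft[, !keep] <- 0 + 0i
  t(apply(ft, 1, function(row) Re(fft(row, inverse = TRUE)) / tt))
}

# Exact orthogonal projection onto {band-limited} intersect {trend-free}:
# P x = B x - (B U) (U' B U)^-1 (B U)' x with B the band mask and U an
# orthonormal basis of span(1, t). One pass, idempotent to machine precision.
project_detrend_band <- function(m, band_hz, tr) {
  tt <- ncol(m)
  t_idx <- seq_len(tt) - (tt + 1) / 2
  u <- cbind(rep(1 / sqrt(tt), tt), t_idx / sqrt(sum(t_idx^2)))
  bu <- t(bandpass_rows(t(u), band_hz, tr))
  g <- crossprod(u, bu)
  bm <- bandpass_rows(m, band_hz, tr)
  # trend directions orthogonal to the band (e.g. DC) are annihilated by the
  # mask already; constrain only directions with real overlap
  eg <- eigen((g + t(g)) / 2, symmetric = TRUE)
  keep <- eg$values > 1e-12
  if (!any(keep)) return(bm)
  w <- bu %*% eg$vectors[, keep, drop = FALSE]
  bm - (m %*% w) %*% (t(w) / eg$values[keep])
}

regress_rows <- function(m, regressors) {
  x <- cbind(1, regressors)
  qr_x <- qr(x)
  t(qr.resid(qr_x, t(m)))
}

#' Temporal preprocessing of regional time series
#'
#' Applies, in order: linear detrend of each regional signal, band-pass
#' filtering by a hard frequency-domain mask (the two are alternated to
#' their common fixed point, which makes the preprocessing operator a true
#' projection and therefore idempotent), nuisance regression (residuals
#' of each signal on the supplied regressors, e.g. motion parameters and mean
#' WM/CSF signals, which are detrended and filtered identically before
#' regression), and z-scoring of each row. A region whose signal is constant
#' (zero variance) at the z-scoring step is an error naming the region:
#' downstream correlations would be undefined.
#'
#' @param ts A `regional_ts`.
#' @param nuisance Optional `T x K` matrix of nuisance regressors (rows =
#'   time points), or `NULL` to skip the regression step.
#' @param band_hz Length-2 numeric `(low, high)` in Hz; must satisfy
#'   `0 < low < high < 1/(2 tr)` (the Nyquist frequency).
#' @return A `regional_ts` with updated data and provenance.
#' @export
preprocess_series <- function(ts, nuisance = NULL, band_hz = c(0.01, 0.1)) {
  stopifnot(inherits(ts, "regional_ts"))
  tt <- ncol(ts$data)
  nyquist <- 1 / (2 * ts$tr_seconds)
  if (length(band_hz) != 2 || band_hz[1] <= 0 || band_hz[1] >= band_hz[2] ||
      band_hz[2] >= nyquist) {
    abort(sprintf("band must satisfy 0 < low < high < Nyquist (%.4g Hz)",
                  nyquist))
  }
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != tt) {
      abort("nuisance regressors must have one row per time point")
    }
  }
  # detrending and the band mask are both orthogonal projections; alternate
  # them to their common fixed point so preprocessing is itself a projection
  # (idempotent: re-running it on its own output changes nothing)
  m <- project_detrend_band(ts$data, band_hz, ts$tr_seconds)
  if (!is.null(nuisance) && ncol(nuisance) > 0) {
    nf <- project_detrend_band(t(nuisance), band_hz, ts$tr_seconds)
    m <- regress_rows(m, t(nf))
  }
  sds <- apply(m, 1, sd)
  tol <- 1e-10 * max(1, max(abs(ts$data)))
  if (any(sds <= tol)) {
    bad <- which(sds <= tol)
    labels <- rownames(ts$data)[bad] %||% as.character(bad)
    abort(paste0("constant (zero-variance) signal after preprocessing in ",
                 "region(s): ", paste(labels, collapse = ", ")))
  }
  m <- (m - rowMeans(m)) / sds
  regional_ts(m, tr_seconds = ts$tr_seconds, band_hz = band_hz,
              provenance = c(ts$provenance, "detrend", "bandpass",
                             if (!is.null(nuisance)) "nuisance_regression",
                             "zscore"),
              subject_id = ts$subject_id)
}

#' Partial correlation matrix of regional time series
#'
#' The partial correlation of regions i and j conditions on all other
#' regions; it is read off the inverse of the sample correlation matrix P as
#' `-P_ij / sqrt(P_ii P_jj)`. With two regions it reduces to the Pearson
#' correlation. If the correlation matrix is near-singular (condition number
#' above `cond_threshold`) a small ridge `lambda * I` with
#' `lambda = 1e-6 * trace(R)/N` is added when `regularize = TRUE`, otherwise
#' the call errors.
#'
#' @param ts A `regional_ts` or a plain regions x time numeric matrix.
#' @param regularize Add a ridge term when the correlation matrix is
#'   ill-conditioned (default `TRUE`).
#' @param cond_threshold Condition-number threshold above which the ridge is
#'   applied (or an error raised).
#' @return Symmetric `N x N` matrix with unit diagonal, entries in \[-1, 1\].
#' @export
partial_correlation_matrix <- function(ts, regularize = TRUE,
                                       cond_threshold = 1e10) {
  m <- if (inherits(ts, "regional_ts")) ts$data else as.matrix(ts)
  n <- nrow(m)
  if (n < 2) abort("need at least two regions")
  if (ncol(m) < 3) abort("too few time points to estimate correlations")
  sds <- apply(m, 1, sd)
  if (any(sds == 0)) {
    abort(paste0("constant region row(s): ",
                 paste(which(sds == 0), collapse = ", ")))
  }
  r <- cor(t(m))
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  cond <- max(ev) / max(min(ev), .Machine$double.eps)
  if (min(ev) <= 0 || cond > cond_threshold) {
    if (!regularize) {
      abort("correlation matrix is singular or ill-conditioned; enable regularize")
    }
    r <- r + diag(1e-6 * sum(diag(r)) / n, n)
  }
  p <- chol2inv(chol(r))
  dd <- sqrt(diag(p))
  pc <- -p / tcrossprod(dd)
  diag(pc) <- 1
  pc[pc > 1] <- 1
  pc[pc < -1] <- -1
  (pc + t(pc)) / 2
}

#' Fisher z-transformation of a correlation coefficient
#'
#' The variance-stabilising `atanh` map; odd and strictly increasing on
#' (-1, 1).
#'
#' @param r Numeric vector of correlations with `|r| < 1`.
#' @return `atanh(r)`.
#' @examples
#' fisher_z(0.5)  # 0.5493061
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1)) {
    abort("fisher_z requires |r| < 1")
  }
  atanh(r)
}

#' Build a functional connectome from preprocessed regional time series
#'
#' Edge weights are Fisher z-transformed partial correlations between
#' regional signals; negative partial correlations are excluded (set to 0),
#' reflecting the unsettled interpretation of negative couplings after
#' nuisance regression. The binary kind sets to 1 every connection with
#' `z > 0` and 0 otherwise.
#'
#' @param ts A `regional_ts` with rows in functional node order (typically
#'   the output of [preprocess_series()]).
#' @param region_table A validated region table supplying the functional node
#'   set, or a node tibble from [functional_nodes()].
#' @param kind `"func_weighted"` or `"func_binary"`.
#' @param ... Passed to [partial_correlation_matrix()].
#' @return A `connectome`.
#' @export
build_functional_connectome <- function(ts, region_table,
                                        kind = c("func_weighted",
                                                 "func_binary"),
                                        ...) {
  kind <- match.arg(kind)
  nodes <- if (inherits(region_table, "region_table") ||
               "volume_mm3" %in% names(region_table)) {
    functional_nodes(region_table)
  } else {
    region_table
  }
  m <- if (inherits(ts, "regional_ts")) ts$data else as.matrix(ts)
  if (nrow(m) != nrow(nodes)) {
    abort(sprintf("time series has %d rows but the functional node set has %d",
                  nrow(m), nrow(nodes)))
  }
  pc <- partial_correlation_matrix(ts, ...)
  diag(pc) <- 0
  w <- matrix(0, nrow(pc), ncol(pc))
  pos <- pc > 0
  # |pc| < 1 off-diagonal except degenerate duplicated series; clamp below 1
  w[pos] <- atanh(pmin(pc[pos], 1 - 1e-15))
  w <- (w + t(w)) / 2
  if (kind == "func_binary") w <- (w > 0) * 1
  subject_id <- if (inherits(ts, "regional_ts")) ts$subject_id else NULL
  new_connectome(w, nodes, kind, subject_id = subject_id)
}

#' Read / write regional time series as TSV with a JSON sidecar
#'
#' Rows are regions in functional node order, columns are time points; the
#' sidecar `<path>.json` stores `tr_seconds` and `subject_id`.
#'
#' @param path File path.
#' @param ts A `regional_ts`.
#' @return A `regional_ts` (`read_regional_ts`) or `path` invisibly.
#' @export
read_regional_ts <- function(path) {
  if (!file.exists(path)) abort(paste0("time-series file not found: ", path))
  m <- as.matrix(readr::read_tsv(path, col_names = FALSE,
                                 show_col_types = FALSE, progress = FALSE))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  regional_ts(unname(m), tr_seconds = meta$tr_seconds,
              subject_id = meta$subject_id)
}

#' @rdname read_regional_ts
#' @export
write_regional_ts <- function(ts, path) {
  readr::write_tsv(as.data.frame(ts$data), path, col_names = FALSE,
                   progress = FALSE)
  jsonlite::write_json(
    list(tr_seconds = ts$tr_seconds, subject_id = ts$subject_id),
    paste0(path, ".json"), auto_unbox = TRUE, null = "null"
  )
  invisible(path)
}

#' Average a voxel-by-time matrix into regional time series
#'
#' Convenience helper for inputs that are not yet region-averaged: each
#' region's signal is the mean over its voxels.
#'
#' @param voxels Voxel x time numeric matrix.
#' @param voxel_region Integer vector assigning each voxel row to a region
#'   (1-based, `1..n_regions`).
#' @param n_regions Number of regions.
#' @param ... Passed to [regional_ts()].
#' @return A `regional_ts` with `n_regions` rows.
#' @export
average_voxels_by_region <- function(voxels, voxel_region, n_regions, ...) {
  voxels <- as.matrix(voxels)
  if (length(voxel_region) != nrow(voxels)) {
    abort("voxel_region must assign every voxel row")
  }
  if (!all(voxel_region %in% seq_len(n_regions))) {
    abort("voxel_region values must lie in 1..n_regions")
  }
  out <- matrix(NA_real_, n_regions, ncol(voxels))
  for (r in seq_len(n_regions)) {
    rows <- voxel_region == r
    if (!any(rows)) abort(paste0("region ", r, " has no voxels"))
    out[r, ] <- colMeans(voxels[rows, , drop = FALSE])
  }
  regional_ts(out, ...)
}
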