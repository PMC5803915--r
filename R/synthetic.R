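#' Configuration for a synthetic two-group cohort
#'
#' Defaults mirror the study design the generator emulates: 9 animals per
#' group (transgenic Alzheimer-model rats vs wild-type controls), a
#' 76-region structural / 54-region functional parcellation, resting-state
#' series of 600 samples at TR = 2 s, control scan ages of 151.11 +/- 12.06
#' days and transgenic ages of 181 +/- 32.6 days (transgenic animals train
#' longer, so they scan later -- the age confound the GLM stage exists for).
#' Parameters with no published counterpart (streamline count model, FA
#' noise, BOLD precision structure) are generator calibrations documented in
#' the methods vignette.
#'
#' @param n_per_group Animals per group (default 9).
#' @param region_table A validated region table, or `NULL` for the packaged
#'   76/54 parcellation.
#' @param seed Integer seed; the cohort is a deterministic function of the
#'   config.
#' @param edge_density Target fraction of region pairs connected by
#'   streamlines (default 0.35).
#' @param streamline_rate Mean streamline count on a connected pair
#'   (default 12).
#' @param fa_base_mean,fa_base_sd Mean and between-pair SD of per-connection
#'   FA (defaults 0.45, 0.08).
#' @param subject_fa_sd SD of the per-subject global FA scaling factor
#'   (default 0.05); this is the between-animal variability that group tests
#'   work against.
#' @param fa_effect Multiplicative FA reduction in the transgenic group
#'   (default 0.15, i.e. transgenic FA = 0.85 x control-level FA).
#' @param func_effect Multiplicative change of planted functional couplings
#'   in the transgenic group (default 0: the study found no global
#'   functional differences).
#' @param regional_effects List of `list(region =, parameter =, delta =,
#'   group =)` entries applied with [plant_regional_effect()].
#' @param age_model Per-group scan-age mean/SD in days.
#' @param behavior_coupling `list(kind, metric, outcome, rho)`: target
#'   Spearman correlation between a global network metric and a behavioral
#'   outcome, induced by a Gaussian copula on ranks. Default couples
#'   fiber-density average strength to the total training-session count at
#'   rho = -0.72 (animals with weaker connectivity learn slower).
#' @param n_timepoints,tr_seconds Resting-state series length and sampling
#'   interval (defaults 600, 2).
#' @param band_hz Frequency band of the simulated BOLD signal.
#' @param func_edge_density Fraction of functional node pairs with a planted
#'   nonzero partial correlation (default 0.08).
#' @param func_partial Planted partial-correlation value (default 0.2).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_per_group = 9,
                          region_table = NULL,
                          seed = 1,
                          edge_density = 0.35,
                          streamline_rate = 12,
                          fa_base_mean = 0.45,
                          fa_base_sd = 0.08,
                          subject_fa_sd = 0.05,
                          fa_effect = 0.15,
                          func_effect = 0,
                          regional_effects = list(),
                          age_model = list(
                            control = c(mean = 151.11, sd = 12.06),
                            transgenic = c(mean = 181, sd = 32.6)
                          ),
                          behavior_coupling = list(
                            kind = "fd_weighted",
                            metric = "avg_strength",
                            outcome = "training_sessions_total",
                            rho = -0.72
                          ),
                          n_timepoints = 600,
                          tr_seconds = 2,
                          band_hz = c(0.01, 0.1),
                          func_edge_density = 0.08,
                          func_partial = 0.2) {
  if (n_per_group < 2) abort("n_per_group must be at least 2")
  if (edge_density <= 0 || edge_density > 1) {
    abort("edge_density must lie in (0, 1]")
  }
  if (fa_effect < 0 || fa_effect >= 1) abort("fa_effect must lie in [0, 1)")
  if (abs(behavior_coupling$rho) >= 1) {
    abort("infeasible behavior coupling: |rho| must be < 1")
  }
  structure(
    list(n_per_group = n_per_group, region_table = region_table, seed = seed,
         edge_density = edge_density, streamline_rate = streamline_rate,
         fa_base_mean = fa_base_mean, fa_base_sd = fa_base_sd,
         subject_fa_sd = subject_fa_sd, fa_effect = fa_effect,
         func_effect = func_effect, regional_effects = regional_effects,
         age_model = age_model, behavior_coupling = behavior_coupling,
         n_timepoints = n_timepoints, tr_seconds = tr_seconds,
         band_hz = band_hz, func_edge_density = func_edge_density,
         func_partial = func_partial),
    class = "cohort_config"
  )
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a synthetic two-group cohort
#'
#' Produces per-subject streamline records, regional time series, nuisance
#' regressors, metadata and behavioral outcomes, with configurable planted
#' effects, plus a ground-truth manifest of everything planted. Region pairs
#' are connected with a probability that decays with the distance between
#' random region centroids, streamline counts are Poisson, lengths scale
#' with centroid distance, and per-streamline FA combines a per-connection
#' mean, a per-subject global scale, and the group-level reduction
#' `1 - fa_effect` for transgenic animals. BOLD series are band-limited
#' Gaussian signals with a planted sparse precision structure, wrapped in a
#' baseline, a linear drift, and motion/WM/CSF nuisance contributions so the
#' preprocessing stage has real work to do.
#'
#' The cohort is a deterministic function of the configuration (same config,
#' byte-identical outputs).
#'
#' @param config A [cohort_config()].
#' @return A `cohort` list: `region_table`, `subjects`, `streamlines`,
#'   `time_series` (named list of `regional_ts`), `nuisance` (named list of
#'   T x K matrices), `manifest`, `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  tab <- config$region_table %||%
    read_region_table(example_region_table_path())
  tab <- validate_region_table(tab)
  nodes_s <- structural_nodes(tab)
  nodes_f <- functional_nodes(tab)
  ns <- nrow(nodes_s)
  nf <- nrow(nodes_f)

  # region centroids in a rat-brain-sized box (mm); distances drive both
  # connection probability and streamline length
  pos <- cbind(runif(ns, 0, 16), runif(ns, 0, 10), runif(ns, 0, 8))
  d <- as.matrix(stats::dist(pos))
  decay <- exp(-d / 5)
  diag(decay) <- 0
  p_connect <- decay * config$edge_density * (ns * (ns - 1)) /
    (2 * sum(decay[upper.tri(decay)]))
  p_connect <- clamp(p_connect, 0, 1)

  # per-connection FA level, shared across the cohort (anatomy), plus noise
  fa_pair <- matrix(0, ns, ns)
  fa_pair[upper.tri(fa_pair)] <- clamp(
    rnorm(ns * (ns - 1) / 2, config$fa_base_mean, config$fa_base_sd),
    0.05, 0.95
  )
  fa_pair <- fa_pair + t(fa_pair)

  # planted functional precision over functional nodes (unit diagonal)
  prec <- plant_precision(nf, config$func_edge_density, config$func_partial)

  n <- 2 * config$n_per_group
  groups <- rep(c("control", "transgenic"), each = config$n_per_group)
  subject_ids <- sprintf("sub%02d", seq_len(n))

  sl_list <- vector("list", n)
  ts_list <- vector("list", n)
  nuis_list <- vector("list", n)
  ages <- numeric(n)
  up <- which(upper.tri(p_connect), arr.ind = TRUE)
  for (s in seq_len(n)) {
    grp <- groups[s]
    group_mult <- if (grp == "transgenic") 1 - config$fa_effect else 1
    subj_scale <- rnorm(1, 1, config$subject_fa_sd)
    present <- runif(nrow(up)) < p_connect[up]
    pairs <- up[present, , drop = FALSE]
    counts <- 1L + rpois(nrow(pairs), config$streamline_rate *
                           exp(-d[pairs] / 10))
    idx <- rep(seq_len(nrow(pairs)), counts)
    n_sl <- length(idx)
    dist_sl <- d[pairs][idx]
    lengths <- dist_sl * runif(n_sl, 1.05, 1.6)
    fa_mean_sl <- fa_pair[pairs][idx] * subj_scale * group_mult
    fa_sl <- clamp(rnorm(n_sl, fa_mean_sl, 0.03), 0.01, 0.99)
    sl_list[[s]] <- tibble(
      subject_id = subject_ids[s],
      start_index = nodes_s$source_index[pairs[idx, 1]],
      end_index = nodes_s$source_index[pairs[idx, 2]],
      length_mm = lengths,
      mean_fa = fa_sl
    )

    prec_s <- prec
    if (grp == "transgenic" && config$func_effect != 0) {
      off <- prec_s - diag(diag(prec_s))
      prec_s <- diag(diag(prec_s)) + off * (1 + config$func_effect)
    }
    signal <- generate_time_series(prec_s, n_timepoints = config$n_timepoints,
                                   tr_seconds = config$tr_seconds,
                                   band_hz = config$band_hz)$data
    tt <- config$n_timepoints
    nuis <- cbind(
      apply(matrix(rnorm(tt * 6, sd = 0.02), tt, 6), 2, cumsum),  # motion
      rnorm(tt, sd = 0.5),                                        # WM mean
      rnorm(tt, sd = 0.5)                                         # CSF mean
    )
    colnames(nuis) <- c(paste0("motion", 1:6), "wm_signal", "csf_signal")
    drift <- outer(rnorm(nf, sd = 0.005), seq_len(tt) - tt / 2)
    nuis_load <- matrix(rnorm(nf * ncol(nuis), sd = 0.3), nf)
    raw <- 100 + drift + 10 * signal + nuis_load %*% t(nuis)
    ts_list[[s]] <- regional_ts(raw, tr_seconds = config$tr_seconds,
                                provenance = "simulated",
                                subject_id = subject_ids[s])
    nuis_list[[s]] <- nuis

    am <- config$age_model[[grp]]
    ages[s] <- round(clamp(rnorm(1, am["mean"], am["sd"]), 90, 365), 1)
  }
  streamlines <- bind_rows(sl_list)
  names(ts_list) <- subject_ids
  names(nuis_list) <- subject_ids

  subjects <- tibble(subject_id = subject_ids, group = groups,
                     age_days = ages)
  subjects <- bind_cols(
    subjects,
    generate_behavior(subjects, streamlines, tab, config)
  )

  manifest <- list(
    seed = config$seed,
    n_per_group = config$n_per_group,
    fa_effect = list(parameter = "mean_fa", group = "transgenic",
                     multiplier = 1 - config$fa_effect),
    func_effect = config$func_effect,
    behavior_coupling = config$behavior_coupling,
    age_model = config$age_model,
    func_structure = list(edge_density = config$func_edge_density,
                          partial_correlation = config$func_partial),
    regional_effects = list()
  )
  cohort <- structure(
    list(region_table = tab, subjects = subjects, streamlines = streamlines,
         time_series = ts_list, nuisance = nuis_list, manifest = manifest,
         config = config),
    class = "cohort"
  )
  for (eff in config$regional_effects) {
    cohort <- do.call(plant_regional_effect, c(list(cohort), eff))
  }
  cohort
}

# sparse symmetric precision with unit diagonal and planted partial
# correlations; kept positive definite by construction check
plant_precision <- function(nf, density, partial) {
  prec <- diag(nf)
  pairs <- which(upper.tri(prec), arr.ind = TRUE)
  chosen <- runif(nrow(pairs)) < density
  # unit-diagonal precision: off-diagonal entry -rho gives partial corr rho
  prec[pairs[chosen, , drop = FALSE]] <- -partial
  prec[lower.tri(prec)] <- t(prec)[lower.tri(prec)]
  # enforce diagonal dominance if the draw was too dense
  rs <- apply(abs(prec), 1, sum) - 1
  if (max(rs) >= 1) {
    scale <- 0.95 / max(rs)
    off <- prec - diag(nf)
    prec <- diag(nf) + off * scale
  }
  prec
}

#' Generate band-limited Gaussian regional time series
#'
#' Samples `n_timepoints` draws from a zero-mean Gaussian with covariance
#' equal to the inverse of the planted precision matrix, then restricts each
#' regional signal to the requested frequency band (a linear filter applied
#' identically to every region preserves the cross-regional correlation
#' structure) and rescales rows to unit variance. Sample partial correlations
#' converge to the planted values as the series lengthens.
#'
#' @param precision Positive-definite `N x N` precision matrix.
#' @param n_timepoints Number of samples (>= 10).
#' @param tr_seconds Sampling interval in seconds.
#' @param seed Optional seed for standalone use; inside [generate_cohort()]
#'   the surrounding RNG state is used.
#' @param band_hz Frequency band of the signal.
#' @return A `regional_ts`.
#' @export
generate_time_series <- function(precision, n_timepoints = 600,
                                 tr_seconds = 2, seed = NULL,
                                 band_hz = c(0.01, 0.1)) {
  precision <- as.matrix(precision)
  nf <- nrow(precision)
  if (nf != ncol(precision) ||
      max(abs(precision - t(precision))) > 1e-10) {
    abort("precision must be a symmetric square matrix")
  }
  ch <- tryCatch(chol(precision),
                 error = function(e) abort("precision must be positive definite"))
  if (n_timepoints < 10) {
    abort("too few time points to carry a band-limited signal (need >= 10)")
  }
  gen <- function() {
    sigma <- chol2inv(ch)
    x <- matrix(rnorm(n_timepoints * nf), n_timepoints, nf) %*% chol(sigma)
    m <- bandpass_rows(t(x), band_hz, tr_seconds)
    sds <- apply(m, 1, sd)
    sds[sds == 0] <- 1
    m <- m / sds
    regional_ts(m, tr_seconds = tr_seconds, band_hz = band_hz,
                provenance = "simulated")
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# Gaussian copula: returns a standard-normal latent whose rank correlation
# with `values` targets rho_s in expectation
couple_latent <- function(values, rho_s) {
  if (abs(rho_s) >= 1) abort("infeasible coupling: |rho| must be < 1")
  n <- length(values)
  u <- qnorm((rank(values, ties.method = "average") - 0.5) / n)
  u <- u / sd(u)
  rho_p <- 2 * sin(pi * rho_s / 6)
  rho_p * u + sqrt(1 - rho_p^2) * rnorm(n)
}

generate_behavior <- function(subjects, streamlines, tab, config) {
  n <- nrow(subjects)
  bc <- config$behavior_coupling
  metric_vals <- vapply(subjects$subject_id, function(sid) {
    sl <- streamlines[streamlines$subject_id == sid, ]
    conn <- build_structural_connectome(sl, tab, kind = bc$kind,
                                        subject_id = sid)
    summarize_connectome(conn)$global[[bc$metric]]
  }, numeric(1))

  latent <- couple_latent(metric_vals, bc$rho)
  tg <- subjects$group == "transgenic"
  sessions_total <- pmax(10, round(40 + 6 * tg + 8 * latent))
  stage5 <- pmax(5, round(0.55 * sessions_total + rnorm(n, 0, 2)))
  trials_total <- rpois(n, ifelse(tg, 450, 550))
  trials_short <- rbinom(n, trials_total, 0.6)
  pct_total <- clamp(rnorm(n, 72, 4), 0, 100)
  out <- tibble(
    training_sessions_stage5 = stage5,
    training_sessions_total = sessions_total,
    dnms_trials_total = trials_total,
    dnms_trials_short = trials_short,
    dnms_trials_long = trials_total - trials_short,
    pct_correct_total = pct_total,
    pct_correct_short = clamp(pct_total + rnorm(n, 2, 2), 0, 100),
    pct_correct_long = clamp(pct_total + rnorm(n, -4, 2), 0, 100)
  )
  if (!bc$outcome %in% names(out)) {
    abort(paste0("unknown behavior outcome: ", bc$outcome))
  }
  out
}

#' Plant a regional effect into a generated cohort
#'
#' Modifies a single region's generative parameter for one group and records
#' the change in the ground-truth manifest. Structural parameters act on the
#' region's incident streamlines (`mean_fa` and `length_mm` are scaled by
#' `1 + delta`, FA clamped to \[0, 1\]); `func_coupling` adds
#' `delta x` (mean signal of the other regions) to the region's BOLD signal,
#' strengthening (or, negative `delta`, weakening) its functional couplings.
#' Plants on different regions commute.
#'
#' @param cohort A `cohort` from [generate_cohort()].
#' @param region A node label (e.g. `"R Medial prefrontal cortex"`) or a
#'   region name (both hemispheres affected).
#' @param parameter `"mean_fa"`, `"length_mm"` or `"func_coupling"`.
#' @param delta Relative change (0 = no change).
#' @param group Which group to perturb (default `"transgenic"`).
#' @return The modified cohort.
#' @export
plant_regional_effect <- function(cohort, region,
                                  parameter = c("mean_fa", "length_mm",
                                                "func_coupling"),
                                  delta = 0, group = "transgenic") {
  stopifnot(inherits(cohort, "cohort"))
  parameter <- match.arg(parameter)
  if (!group %in% c("control", "transgenic")) abort("unknown group")
  subj <- cohort$subjects$subject_id[cohort$subjects$group == group]

  if (parameter %in% c("mean_fa", "length_mm")) {
    nodes <- structural_nodes(cohort$region_table)
    hit <- nodes$label == region | nodes$region_name == region
    if (!any(hit)) abort(paste0("unknown region: ", region))
    idx <- nodes$source_index[hit]
    sl <- cohort$streamlines
    target <- sl$subject_id %in% subj &
      (sl$start_index %in% idx | sl$end_index %in% idx)
    if (parameter == "mean_fa") {
      sl$mean_fa[target] <- clamp(sl$mean_fa[target] * (1 + delta), 0, 1)
    } else {
      sl$length_mm[target] <- sl$length_mm[target] * (1 + delta)
    }
    cohort$streamlines <- sl
  } else {
    nodes <- functional_nodes(cohort$region_table)
    hit <- which(nodes$label == region | nodes$region_name == region)
    if (length(hit) == 0) abort(paste0("unknown functional region: ", region))
    for (sid in subj) {
      m <- cohort$time_series[[sid]]$data
      for (i in hit) {
        m[i, ] <- m[i, ] + delta * colMeans(m[-i, , drop = FALSE])
      }
      cohort$time_series[[sid]]$data <- m
    }
  }
  cohort$manifest$regional_effects <- c(
    cohort$manifest$regional_effects,
    list(list(region = region, parameter = parameter, delta = delta,
              group = group))
  )
  cohort
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects (%d per group), %d streamlines, %d regions\n",
              nrow(x$subjects), x$config$n_per_group,
              nrow(x$streamlines), nrow(x$region_table)))
  invisible(x)
}

#' Write / read a cohort directory
#'
#' Emits the on-disk layout the pipeline consumes: `region_table.tsv`,
#' `subjects.csv`, `streamlines/<subject>.tsv`, `timeseries/<subject>.tsv`
#' (+ JSON sidecars), `nuisance/<subject>.tsv`, `manifest.json`.
#'
#' @param cohort A `cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir` invisibly (`write_cohort`) or a `cohort` (`read_cohort`).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sub in c("streamlines", "timeseries", "nuisance")) {
    dir.create(file.path(dir, sub), showWarnings = FALSE)
  }
  readr::write_tsv(cohort$region_table, file.path(dir, "region_table.tsv"),
                   progress = FALSE, na = "")
  readr::write_csv(cohort$subjects, file.path(dir, "subjects.csv"),
                   progress = FALSE)
  for (sid in cohort$subjects$subject_id) {
    write_streamlines(
      cohort$streamlines[cohort$streamlines$subject_id == sid, ],
      file.path(dir, "streamlines", paste0(sid, ".tsv"))
    )
    write_regional_ts(cohort$time_series[[sid]],
                      file.path(dir, "timeseries", paste0(sid, ".tsv")))
    readr::write_tsv(as.data.frame(cohort$nuisance[[sid]]),
                     file.path(dir, "nuisance", paste0(sid, ".tsv")),
                     progress = FALSE)
  }
  jsonlite::write_json(cohort$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  tab <- read_region_table(file.path(dir, "region_table.tsv"))
  subjects <- readr::read_csv(file.path(dir, "subjects.csv"),
                              show_col_types = FALSE, progress = FALSE)
  sl <- list()
  ts <- list()
  nuis <- list()
  for (sid in subjects$subject_id) {
    sl_path <- file.path(dir, "streamlines", paste0(sid, ".tsv"))
    ts_path <- file.path(dir, "timeseries", paste0(sid, ".tsv"))
    nu_path <- file.path(dir, "nuisance", paste0(sid, ".tsv"))
    for (p in c(sl_path, ts_path, nu_path)) {
      if (!file.exists(p)) {
        abort(paste0("missing file for subject ", sid, ": ", p))
      }
    }
    sl[[sid]] <- read_streamlines(sl_path)
    ts[[sid]] <- read_regional_ts(ts_path)
    nuis[[sid]] <- as.matrix(readr::read_tsv(nu_path, show_col_types = FALSE,
                                             progress = FALSE))
  }
  manifest_path <- file.path(dir, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path)
  } else {
    list()
  }
  structure(
    list(region_table = tab, subjects = subjects,
         streamlines = bind_rows(sl), time_series = ts, nuisance = nuis,
         manifest = manifest, config = NULL),
    class = "cohort"
  )
}
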