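#' Run the full connectomics analysis pipeline
#'
#' Reproduces the analysis order of the study this package implements:
#' per-subject connectome construction (structural: binary / FA-weighted /
#' fiber-density-weighted from streamlines; functional: weighted and binary
#' from preprocessed regional time series), graph-metric computation, group
#' statistics (Kruskal-Wallis and age-adjusted GLM with per-family FDR over
#' regions) and a Spearman screen of every metric against every behavioral
#' outcome.
#'
#' @param config Either a `cohort` object, a path to a cohort directory
#'   (see [write_cohort()]), a path to a YAML file with an `input_dir` entry,
#'   or a list with entries `cohort`/`input_dir` plus any of the options
#'   below.
#' @param kinds Connectome kinds to build (default all five).
#' @param band_hz Band-pass for functional preprocessing (default
#'   `c(0.01, 0.1)` Hz).
#' @param alpha FDR significance level used in reporting (default 0.05).
#' @param r_threshold Correlation screening threshold (default 0.7).
#' @param outcomes Behavior columns to screen (default: every behavior
#'   column present in the subject table).
#' @param out_dir Optional output directory; when given, all result tables,
#'   per-subject connectome matrices and a run manifest are written there.
#' @return A `pipeline_run` list: `connectomes` (per subject, per kind),
#'   `metrics`, `stats`, `correlations`, `alpha`, `r_threshold`, `out_dir`.
#' @examples
#' \donttest{
#' cohort <- generate_cohort(cohort_config(seed = 7))
#' run <- run_pipeline(cohort)
#' dplyr::filter(tidy(run$stats), p_fdr < 0.05)
#' }
#' @export
run_pipeline <- function(config,
                         kinds = c("binary", "fa_weighted", "fd_weighted",
                                   "func_weighted", "func_binary"),
                         band_hz = c(0.01, 0.1),
                         alpha = 0.05,
                         r_threshold = 0.7,
                         outcomes = NULL,
                         out_dir = NULL) {
  opts <- list(kinds = kinds, band_hz = band_hz, alpha = alpha,
               r_threshold = r_threshold, outcomes = outcomes,
               out_dir = out_dir)
  if (is.character(config) && length(config) == 1) {
    if (dir.exists(config)) {
      cohort <- read_cohort(config)
    } else if (file.exists(config)) {
      yml <- yaml::read_yaml(config)
      if (is.null(yml$input_dir)) {
        abort("YAML config must name an input_dir cohort directory")
      }
      opts <- modifyList(opts, yml[intersect(names(yml), names(opts))])
      if (!is.null(yml$band_hz)) opts$band_hz <- as.numeric(yml$band_hz)
      cohort <- read_cohort(yml$input_dir)
    } else {
      abort(paste0("config path does not exist: ", config))
    }
  } else if (inherits(config, "cohort")) {
    cohort <- config
  } else if (is.list(config)) {
    opts <- modifyList(opts, config[intersect(names(config), names(opts))])
    cohort <- config$cohort %||%
      (if (!is.null(config$input_dir)) read_cohort(config$input_dir)
       else abort("config list needs a cohort or an input_dir"))
  } else {
    abort("config must be a cohort, a directory, a YAML path or a list")
  }
  if (length(opts$kinds) == 0) abort("at least one connectome kind required")

  structural_kinds <- intersect(opts$kinds,
                                c("binary", "fa_weighted", "fd_weighted"))
  functional_kinds <- intersect(opts$kinds,
                                c("func_weighted", "func_binary"))

  subjects <- cohort$subjects
  conns <- list()
  for (sid in subjects$subject_id) {
    sl <- cohort$streamlines[cohort$streamlines$subject_id == sid, ]
    if (length(structural_kinds) > 0 && nrow(sl) == 0) {
      abort(paste0("no streamlines for subject ", sid,
                   " (stage: structural connectome)"))
    }
    for (kind in structural_kinds) {
      conns[[paste(sid, kind, sep = ".")]] <- tryCatch(
        build_structural_connectome(sl, cohort$region_table, kind,
                                    subject_id = sid),
        error = function(e) {
          abort(paste0("subject ", sid, ", structural connectome (", kind,
                       "): ", conditionMessage(e)))
        }
      )
    }
    if (length(functional_kinds) > 0) {
      ts <- cohort$time_series[[sid]]
      if (is.null(ts)) {
        abort(paste0("missing time series for subject ", sid,
                     " (stage: functional connectome)"))
      }
      pre <- tryCatch(
        preprocess_series(ts, nuisance = cohort$nuisance[[sid]],
                          band_hz = opts$band_hz),
        error = function(e) {
          abort(paste0("subject ", sid, ", preprocessing: ",
                       conditionMessage(e)))
        }
      )
      for (kind in functional_kinds) {
        conns[[paste(sid, kind, sep = ".")]] <- tryCatch(
          build_functional_connectome(pre, cohort$region_table, kind),
          error = function(e) {
            abort(paste0("subject ", sid, ", functional connectome (", kind,
                         "): ", conditionMessage(e)))
          }
        )
      }
    }
  }

  metrics <- connectome_metrics(conns)
  stats_report <- group_metric_tests(metrics, subjects)
  behavior_cols <- opts$outcomes %||%
    intersect(names(subjects),
              c("training_sessions_stage5", "training_sessions_total",
                "dnms_trials_total", "dnms_trials_short", "dnms_trials_long",
                "pct_correct_total", "pct_correct_short",
                "pct_correct_long"))
  correlations <- behavior_correlation_screen(metrics, subjects,
                                              behavior_cols,
                                              threshold = opts$r_threshold)
  run <- structure(
    list(connectomes = conns, metrics = metrics, stats = stats_report,
         correlations = correlations, subjects = subjects,
         alpha = opts$alpha, r_threshold = opts$r_threshold,
         out_dir = opts$out_dir),
    class = "pipeline_run"
  )
  if (!is.null(opts$out_dir)) write_pipeline_run(run, opts$out_dir)
  run
}

write_pipeline_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "connectomes"), showWarnings = FALSE)
  for (nm in names(run$connectomes)) {
    write_connectome(run$connectomes[[nm]],
                     file.path(out_dir, "connectomes", paste0(nm, ".csv")))
  }
  readr::write_csv(run$metrics, file.path(out_dir, "metrics.csv"),
                   progress = FALSE)
  readr::write_csv(tidy(run$stats), file.path(out_dir, "group_stats.csv"),
                   progress = FALSE)
  readr::write_csv(run$correlations,
                   file.path(out_dir, "behavior_correlations.csv"),
                   progress = FALSE)
  jsonlite::write_json(
    list(alpha = run$alpha, r_threshold = run$r_threshold,
         n_subjects = nrow(run$subjects),
         n_connectomes = length(run$connectomes),
         timestamp = format(Sys.time(), tz = "UTC"),
         package_version = as.character(utils::packageVersion("ratconnectome"))),
    file.path(out_dir, "run_manifest.json"), auto_unbox = TRUE
  )
  writeLines(pipeline_report(run), file.path(out_dir, "report.md"))
  invisible(out_dir)
}

#' Human-readable summary of a pipeline run
#'
#' Lists group differences surviving FDR correction and behavior-metric
#' correlations above the screening threshold, mirroring how connectome
#' studies report their findings (global metrics, regional structural
#' findings, regional functional findings, correlation table).
#'
#' @param run A `pipeline_run` from [run_pipeline()], or the path of a run
#'   directory written by it.
#' @return Character vector of markdown lines.
#' @export
pipeline_report <- function(run) {
  if (is.character(run)) {
    stats_path <- file.path(run, "group_stats.csv")
    corr_path <- file.path(run, "behavior_correlations.csv")
    manifest_path <- file.path(run, "run_manifest.json")
    if (!all(file.exists(c(stats_path, corr_path, manifest_path)))) {
      abort(paste0("incomplete run directory: ", run))
    }
    manifest <- jsonlite::read_json(manifest_path)
    stats_tbl <- readr::read_csv(stats_path, show_col_types = FALSE,
                                 progress = FALSE)
    corr_tbl <- readr::read_csv(corr_path, show_col_types = FALSE,
                                progress = FALSE)
    alpha <- manifest$alpha
    r_threshold <- manifest$r_threshold
  } else {
    stopifnot(inherits(run, "pipeline_run"))
    stats_tbl <- tidy(run$stats)
    corr_tbl <- run$correlations
    alpha <- run$alpha
    r_threshold <- run$r_threshold
  }
  sig <- stats_tbl[stats_tbl$p_fdr < alpha & stats_tbl$scope == "node", ]
  sig_global <- stats_tbl[stats_tbl$p_raw < alpha &
                            stats_tbl$scope == "global", ]
  flagged <- corr_tbl[corr_tbl$flagged, ]
  lines <- c(
    "# Connectome analysis report", "",
    sprintf("FDR alpha: %g; correlation threshold |r| > %g", alpha,
            r_threshold), "",
    "## Global group differences (raw p < alpha)", ""
  )
  lines <- c(lines, if (nrow(sig_global) == 0) "(none)" else sprintf(
    "- %s %s [%s]: p = %.4f, %s", sig_global$connectome_kind,
    sig_global$metric, sig_global$test, sig_global$p_raw,
    sig_global$direction
  ))
  lines <- c(lines, "", "## Regional group differences (FDR p < alpha)", "")
  lines <- c(lines, if (nrow(sig) == 0) "(none)" else sprintf(
    "- %s: %s %s [%s], FDR p = %.4f, %s", sig$region, sig$connectome_kind,
    sig$metric, sig$test, sig$p_fdr, sig$direction
  ))
  lines <- c(lines, "",
             sprintf("## Strong behavior correlations (|r| > %g)",
                     r_threshold), "")
  lines <- c(lines, if (nrow(flagged) == 0) "(none)" else sprintf(
    "- %s ~ %s %s (%s): r = %.4f", flagged$behavior_outcome,
    flagged$connectome_kind, flagged$metric, flagged$region,
    flagged$spearman_r
  ))
  lines
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> %d connectomes, %d metric rows, %d tests\n",
              length(x$connectomes), nrow(x$metrics), nrow(x$stats)))
  invisible(x)
}
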