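#' Two-group Kruskal-Wallis rank test
#'
#' Rank test on midranks with tie correction; the p-value comes from the
#' chi-square reference with 1 degree of freedom (two groups). An optional
#' exact mode enumerates every assignment of the pooled values to the two
#' groups and returns the permutation p-value of H, practical for up to
#' about 8 observations per group.
#'
#' If every pooled value is identical the statistic is 0 and p is 1 (no
#' separation, not an error).
#'
#' @param a,b Numeric samples, each of size >= 2.
#' @param exact Use the exhaustive permutation distribution of H.
#' @return A tibble with columns `statistic` (H), `p_value`, `method`.
#' @examples
#' kruskal_wallis(c(1, 2, 3), c(4, 5, 6))$statistic  # 3.857
#' @export
kruskal_wallis <- function(a, b, exact = FALSE) {
  if (length(a) < 2 || length(b) < 2) {
    abort("each sample needs at least 2 observations")
  }
  if (any(!is.finite(c(a, b)))) abort("samples must be finite")
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1) {
    return(tibble(statistic = 0, p_value = 1,
                  method = "kruskal_wallis_chisq"))
  }
  if (exact) {
    h_obs <- kw_statistic(pooled, seq_along(a))
    combos <- utils::combn(length(pooled), length(a))
    h_perm <- apply(combos, 2, function(idx) kw_statistic(pooled, idx))
    p <- mean(h_perm >= h_obs - 1e-12)
    return(tibble(statistic = h_obs, p_value = p,
                  method = "kruskal_wallis_exact"))
  }
  kt <- kruskal.test(list(a, b))
  tibble(statistic = unname(kt$statistic), p_value = kt$p.value,
         method = "kruskal_wallis_chisq")
}

# H on midranks with tie correction, for a given index set of group A
kw_statistic <- function(pooled, idx_a) {
  n <- length(pooled)
  r <- rank(pooled)
  na <- length(idx_a)
  nb <- n - na
  ra <- mean(r[idx_a])
  rb <- mean(r[-idx_a])
  h <- 12 / (n * (n + 1)) * (na * (ra - (n + 1) / 2)^2 +
                             nb * (rb - (n + 1) / 2)^2)
  ties <- table(pooled)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (correction == 0) return(0)
  h / correction
}

#' Age-adjusted group comparison by a Gaussian GLM
#'
#' Fits `value ~ group + age` with identity link and Gaussian family and
#' reports the group coefficient (transgenic minus control) with its
#' two-sided p-value. The age covariate absorbs the confound created when
#' scan age depends on how long each animal needed to reach the behavioral
#' criterion. If ages are constant the covariate is dropped and the model
#' reduces to a two-sample comparison; if group is perfectly collinear with
#' age the fit errors naming the collinearity.
#'
#' @param values Numeric vector of per-subject metric values.
#' @param subjects Data frame with columns `group` (`"control"` /
#'   `"transgenic"`) and `age_days`, aligned with `values`.
#' @return A tibble with `effect` (group coefficient), `se`, `statistic`,
#'   `p_value`, `age_effect`, `direction`.
#' @export
glm_group_age <- function(values, subjects) {
  if (length(values) != nrow(subjects)) {
    abort("values and subjects must align")
  }
  if (!all(c("group", "age_days") %in% names(subjects))) {
    abort("subjects needs columns group and age_days")
  }
  grp <- factor(subjects$group, levels = c("control", "transgenic"))
  if (any(is.na(grp))) abort("group must be control or transgenic")
  if (length(unique(grp)) < 2) abort("both groups must be represented")
  df <- data.frame(value = values, group = grp, age = subjects$age_days)
  fit <- glm(value ~ group + age, data = df, family = stats::gaussian())
  cf_all <- coef(fit)
  if (is.na(cf_all["grouptransgenic"])) {
    abort("rank-deficient design: group is collinear with age/intercept")
  }
  if (is.na(cf_all["age"]) && length(unique(df$age)) > 1) {
    abort("rank-deficient design: age is collinear with group")
  }
  cf <- summary(fit)$coefficients
  row <- cf["grouptransgenic", ]
  age_effect <- if ("age" %in% rownames(cf)) cf["age", "Estimate"] else NA_real_
  tibble(
    effect = unname(row["Estimate"]),
    se = unname(row["Std. Error"]),
    statistic = unname(row["t value"]),
    p_value = unname(row["Pr(>|t|)"]),
    age_effect = age_effect,
    direction = if (row["Estimate"] < 0) "control > transgenic"
                else "transgenic > control"
  )
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values, clipped to \[0, 1\], in the input order.
#' Adjusted values are never smaller than the raw ones.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
fdr_adjust <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(pvals, method = "BH")
}

#' Spearman correlation screen of network metrics against behavior
#'
#' Computes the Spearman rank correlation between each metric column and a
#' behavioral outcome over subjects, flagging strong correlations with
#' `|r|` strictly above the threshold (0.7 by default, the conventional
#' cut for reporting). Pairs where either vector is constant have an
#' undefined rank correlation; such rows are dropped with a warning.
#'
#' @param metric_values Numeric vector (one metric) or data frame of metric
#'   columns, rows = subjects.
#' @param behavior Numeric vector of the behavioral outcome, same subjects.
#' @param threshold Flagging threshold on `|r|` (default 0.7).
#' @return A tibble with `metric`, `spearman_r`, `n`, `flagged`.
#' @export
spearman_screen <- function(metric_values, behavior, threshold = 0.7) {
  if (is.numeric(metric_values)) {
    metric_values <- tibble(metric = metric_values)
  }
  metric_values <- as_tibble(metric_values)
  if (nrow(metric_values) != length(behavior)) {
    abort("metric values and behavior must cover the same subjects")
  }
  if (nrow(metric_values) < 3) abort("need at least 3 paired observations")
  rows <- purrr::imap(metric_values, function(v, nm) {
    ok <- is.finite(v) & is.finite(behavior)
    if (sum(ok) < 3) {
      warn(paste0("screen '", nm, "': fewer than 3 complete pairs; skipped"))
      return(NULL)
    }
    if (sd(v[ok]) == 0 || sd(behavior[ok]) == 0) {
      warn(paste0("screen '", nm,
                  "': constant vector, correlation undefined; skipped"))
      return(NULL)
    }
    r <- cor(v[ok], behavior[ok], method = "spearman")
    tibble(metric = nm, spearman_r = r, n = sum(ok),
           flagged = abs(r) > threshold)
  })
  bind_rows(rows)
}

#' Group statistics for a tidy metric table
#'
#' For every (connectome kind, metric, region) the two groups are compared
#' with the Kruskal-Wallis rank test and with the age-adjusted Gaussian GLM.
#' Within each (kind, metric, test) family the regional p-values are
#' FDR-adjusted across regions by Benjamini-Hochberg; global metrics form
#' singleton families (no multiplicity).
#'
#' @param metrics Tidy metric table from [connectome_metrics()].
#' @param subjects Subject table with `subject_id`, `group`, `age_days`.
#' @return A `stats_report` tibble with columns `family`, `connectome_kind`,
#'   `metric`, `region`, `scope`, `test`, `statistic`, `effect`, `p_raw`,
#'   `p_fdr`, `direction`.
#' @export
group_metric_tests <- function(metrics, subjects) {
  stopifnot(all(c("subject_id", "group", "age_days") %in% names(subjects)))
  dat <- left_join(metrics, subjects, by = "subject_id")
  if (any(is.na(dat$group))) {
    abort("metric table contains subjects missing from the subject table")
  }
  dat$region <- ifelse(dat$scope == "global", "global", dat$node_label)
  cells <- dat |>
    group_by(.data$connectome_kind, .data$metric_name, .data$scope,
             .data$region) |>
    tidyr::nest() |>
    ungroup()
  res <- purrr::pmap_dfr(
    list(cells$connectome_kind, cells$metric_name, cells$scope,
         cells$region, cells$data),
    function(kind, metric, scope, region, d) {
      a <- d$value[d$group == "control"]
      b <- d$value[d$group == "transgenic"]
      kw <- kruskal_wallis(a, b)
      med_diff <- stats::median(b) - stats::median(a)
      kw_row <- tibble(
        connectome_kind = kind, metric = metric, region = region,
        scope = scope, test = "kruskal_wallis",
        statistic = kw$statistic, effect = med_diff, p_raw = kw$p_value,
        direction = if (med_diff < 0) "control > transgenic"
                    else "transgenic > control"
      )
      gl <- glm_group_age(d$value, d)
      glm_row <- tibble(
        connectome_kind = kind, metric = metric, region = region,
        scope = scope, test = "glm_age_adjusted",
        statistic = gl$statistic, effect = gl$effect, p_raw = gl$p_value,
        direction = gl$direction
      )
      bind_rows(kw_row, glm_row)
    }
  )
  res <- res |>
    group_by(.data$connectome_kind, .data$metric, .data$test, .data$scope) |>
    mutate(p_fdr = fdr_adjust(.data$p_raw)) |>
    ungroup() |>
    mutate(family = paste(.data$connectome_kind, .data$metric, sep = ":")) |>
    select("family", "connectome_kind", "metric", "region", "scope",
           "test", "statistic", "effect", "p_raw", "p_fdr", "direction")
  class(res) <- c("stats_report", class(res))
  res
}

#' Behavior correlation screen over a tidy metric table
#'
#' Screens every (connectome kind, metric, region) against every behavioral
#' outcome column, reporting the Spearman correlation and flagging
#' `|r| > threshold`.
#'
#' @param metrics Tidy metric table from [connectome_metrics()].
#' @param subjects Subject table with `subject_id` and the outcome columns.
#' @param outcomes Character vector of behavior column names in `subjects`.
#' @param threshold Flagging threshold (default 0.7).
#' @return A tibble with `connectome_kind`, `metric`, `region`,
#'   `behavior_outcome`, `spearman_r`, `n`, `flagged`.
#' @export
behavior_correlation_screen <- function(metrics, subjects, outcomes,
                                        threshold = 0.7) {
  missing <- setdiff(outcomes, names(subjects))
  if (length(missing) > 0) {
    abort(paste0("outcome column(s) not in subjects: ",
                 paste(missing, collapse = ", ")))
  }
  dat <- left_join(metrics, subjects, by = "subject_id")
  dat$region <- ifelse(dat$scope == "global", "global", dat$node_label)
  cells <- dat |>
    group_by(.data$connectome_kind, .data$metric_name, .data$region) |>
    tidyr::nest() |>
    ungroup()
  purrr::pmap_dfr(
    list(cells$connectome_kind, cells$metric_name, cells$region, cells$data),
    function(kind, metric, region, d) {
      rows <- purrr::map(outcomes, function(oc) {
        scr <- suppressWarnings(
          spearman_screen(d$value, d[[oc]], threshold = threshold)
        )
        if (is.null(scr) || nrow(scr) == 0) return(NULL)
        tibble(connectome_kind = kind, metric = metric, region = region,
               behavior_outcome = oc, spearman_r = scr$spearman_r,
               n = scr$n, flagged = scr$flagged)
      })
      bind_rows(rows)
    }
  )
}

#' @export
tidy.stats_report <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @export
glance.stats_report <- function(x, ...) {
  tibble(
    n_tests = nrow(x),
    n_significant_raw = sum(x$p_raw <= 0.05),
    n_significant_fdr = sum(x$p_fdr <= 0.05),
    n_families = length(unique(x$family))
  )
}

#' P-value overview of a group-statistics report
#'
#' @param object A `stats_report`.
#' @param alpha Significance line to draw (default 0.05).
#' @param ... Unused.
#' @return A ggplot object showing FDR-adjusted p-values per family.
#' @export
autoplot.stats_report <- function(object, alpha = 0.05, ...) {
  df <- as_tibble(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$family, y = .data$p_fdr,
                                   colour = .data$test,
                                   shape = .data$scope)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = alpha, linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "FDR-adjusted p", colour = NULL,
                  shape = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
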