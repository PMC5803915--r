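test_that("Kruskal-Wallis handles separation, ties and degenerate input", {
  res <- kruskal_wallis(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, oracle_kw_h(c(1, 2, 3), c(4, 5, 6)),
               tolerance = 1e-12)
  expect_equal(res$statistic, 3.857143, tolerance = 1e-6)

  same <- kruskal_wallis(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  expect_error(kruskal_wallis(1, c(1, 2)), "at least 2")

  # invariance under strictly monotone transforms of the pooled data
  set.seed(41)
  a <- rnorm(6)
  b <- rnorm(7, 1)
  expect_equal(kruskal_wallis(a, b)$statistic,
               kruskal_wallis(exp(a), exp(b))$statistic, tolerance = 1e-12)
})

test_that("exact permutation p agrees with an exhaustive oracle", {
  set.seed(42)
  for (rep in 1:4) {
    na <- sample(3:6, 1)
    nb <- sample(3:6, 1)
    a <- round(rnorm(na), 1)  # rounding forces occasional ties
    b <- round(rnorm(nb, 0.8), 1)
    res <- kruskal_wallis(a, b, exact = TRUE)
    expect_equal(res$p_value, oracle_kw_perm_p(a, b), tolerance = 1e-12)
  }
  # the chi-square approximation should be near the exact p for moderate n
  a <- rnorm(7)
  b <- rnorm(7, 1)
  expect_lt(abs(kruskal_wallis(a, b, exact = TRUE)$p_value -
                  kruskal_wallis(a, b)$p_value), 0.1)
})

test_that("the age-adjusted GLM reduces to a t-test with constant ages", {
  set.seed(43)
  subjects <- tibble::tibble(
    group = rep(c("control", "transgenic"), each = 8),
    age_days = 150
  )
  values <- rnorm(16) + (subjects$group == "transgenic") * 0.8
  res <- glm_group_age(values, subjects)
  tt <- stats::t.test(values ~ subjects$group, var.equal = TRUE)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-10)
  expect_equal(res$effect, unname(tt$estimate[2] - tt$estimate[1]),
               tolerance = 1e-10)
})

test_that("the GLM recovers a planted age slope with a null group effect", {
  set.seed(44)
  ages <- c(rnorm(60, 150, 12), rnorm(60, 180, 30))
  subjects <- tibble::tibble(
    group = rep(c("control", "transgenic"), each = 60),
    age_days = ages
  )
  values <- 2 * ages + rnorm(120, sd = 3)
  res <- glm_group_age(values, subjects)
  expect_equal(res$age_effect, 2, tolerance = 0.05)
  expect_gt(res$p_value, 0.01)
})

test_that("a group-age confounded design errors naming the collinearity", {
  subjects <- tibble::tibble(
    group = rep(c("control", "transgenic"), each = 3),
    age_days = rep(c(150, 180), each = 3)
  )
  expect_error(glm_group_age(rnorm(6), subjects), "collinear")
  one_group <- tibble::tibble(group = rep("control", 4), age_days = rnorm(4))
  expect_error(glm_group_age(rnorm(4), one_group), "both groups")
})

test_that("age adjustment protects against the scan-age confound", {
  # transgenic animals scan later; the metric declines with age but has no
  # group effect: the naive rank test is fooled, the GLM is calibrated
  set.seed(45)
  n_sim <- 400
  n <- 9
  glm_reject <- logical(n_sim)
  kw_reject <- logical(n_sim)
  for (s in seq_len(n_sim)) {
    ages <- c(rnorm(n, 151, 12), rnorm(n, 181, 20))
    subjects <- tibble::tibble(
      group = rep(c("control", "transgenic"), each = n),
      age_days = ages
    )
    values <- -0.02 * ages + rnorm(2 * n, sd = 0.15)
    glm_reject[s] <- glm_group_age(values, subjects)$p_value < 0.05
    kw_reject[s] <- kruskal_wallis(values[1:n],
                                   values[(n + 1):(2 * n)])$p_value < 0.05
  }
  expect_lt(mean(glm_reject), 0.09)
  expect_gt(mean(kw_reject), 0.15)  # the naive test is anticonservative
})

test_that("BH adjustment reproduces hand-computed step-up cases", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(rep(0.2, 5)), rep(0.2, 5))
  # hand step-up: sorted p * m / rank, cumulative minimum from the top
  expect_equal(fdr_adjust(c(0.01, 0.4, 0.03)), c(0.03, 0.4, 0.045))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_equal(fdr_adjust(numeric(0)), numeric(0))
})

test_that("BH adjustment never decreases p and preserves the rejection nesting", {
  set.seed(46)
  for (rep in 1:10) {
    p <- runif(sample(3:40, 1))^2
    adj <- fdr_adjust(p)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
    expect_true(all(which(adj <= 0.05) %in% which(p <= 0.05)))
  }
})

test_that("the Spearman screen flags strong monotone relationships", {
  metric <- c(1, 2, 3, 4, 5)
  up <- spearman_screen(metric, metric^3 + 10)
  expect_equal(up$spearman_r, 1)
  expect_true(up$flagged)
  down <- spearman_screen(metric, -exp(metric))
  expect_equal(down$spearman_r, -1)
  expect_true(down$flagged)

  # rank-then-Pearson oracle on small random pairs
  set.seed(47)
  for (rep in 1:10) {
    n <- sample(4:6, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    expect_equal(spearman_screen(x, y)$spearman_r, oracle_spearman(x, y),
                 tolerance = 1e-12)
  }

  # monotone-transform invariance of the rank correlation
  x <- rnorm(10)
  y <- rnorm(10)
  expect_equal(spearman_screen(exp(x), y)$spearman_r,
               spearman_screen(x, y)$spearman_r)

  expect_warning(out <- spearman_screen(rep(1, 5), rnorm(5)), "constant")
  expect_equal(nrow(out), 0)
  expect_error(spearman_screen(1:2, 1:2), "at least 3")
})

test_that("group tests produce per-family FDR and coherent directions", {
  set.seed(48)
  tab <- make_region_table(ns = 6, nf = 4)
  subjects <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:12),
    group = rep(c("control", "transgenic"), each = 6),
    age_days = c(rnorm(6, 150, 10), rnorm(6, 180, 20))
  )
  conns <- lapply(seq_len(12), function(i) {
    m <- 40
    sl <- tibble::tibble(
      start_index = sample(6, m, TRUE), end_index = sample(6, m, TRUE),
      length_mm = runif(m, 1, 20),
      mean_fa = runif(m, 0.3, 0.7) * ifelse(i > 6, 0.7, 1)
    )
    build_structural_connectome(sl, tab, "fa_weighted",
                                subject_id = subjects$subject_id[i])
  })
  metrics <- connectome_metrics(conns)
  report <- group_metric_tests(metrics, subjects)
  expect_s3_class(report, "stats_report")
  expect_true(all(report$p_fdr >= report$p_raw - 1e-15))
  expect_true(all(report$p_fdr <= 1))
  expect_setequal(unique(report$test),
                  c("kruskal_wallis", "glm_age_adjusted"))
  # the planted global FA reduction must come out control > transgenic
  g <- dplyr::filter(report, scope == "global", metric == "avg_strength",
                     test == "kruskal_wallis")
  expect_equal(g$direction, "control > transgenic")
  expect_lt(g$p_raw, 0.05)

  gl <- glance(report)
  expect_equal(gl$n_tests, nrow(report))

  corr <- behavior_correlation_screen(
    metrics, dplyr::mutate(subjects, sessions = rnorm(12)), "sessions"
  )
  expect_true(all(corr$flagged == (abs(corr$spearman_r) > 0.7)))
})
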