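test_that("cohort generation is a deterministic function of the config", {
  cfg <- small_cohort_config(seed = 101)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$streamlines, c2$streamlines)
  expect_identical(c1$subjects, c2$subjects)
  expect_identical(c1$time_series, c2$time_series)
  c3 <- generate_cohort(small_cohort_config(seed = 102))
  expect_false(identical(c1$streamlines, c3$streamlines))
})

test_that("config validation catches infeasible settings", {
  expect_error(cohort_config(n_per_group = 1), "at least 2")
  expect_error(cohort_config(edge_density = 0), "edge_density")
  expect_error(cohort_config(fa_effect = 1), "fa_effect")
  expect_error(cohort_config(behavior_coupling = list(
    kind = "fd_weighted", metric = "avg_strength",
    outcome = "training_sessions_total", rho = 1
  )), "infeasible")
})

test_that("generated files parse through every reader and validator", {
  cohort <- generate_cohort(small_cohort_config(seed = 103, n_per_group = 2))
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  back <- read_cohort(dir)
  expect_equal(nrow(back$subjects), 4)
  expect_equal(as.data.frame(back$region_table),
               as.data.frame(cohort$region_table))
  expect_equal(back$streamlines$length_mm, cohort$streamlines$length_mm,
               tolerance = 1e-12)
  # every subject's streamlines validate against the structural node count
  ns <- nrow(structural_nodes(back$region_table))
  for (sid in back$subjects$subject_id) {
    sl <- back$streamlines[back$streamlines$subject_id == sid, ]
    expect_silent(validate_streamlines(sl, ns))
    expect_s3_class(back$time_series[[sid]], "regional_ts")
    expect_equal(nrow(back$time_series[[sid]]$data),
                 nrow(functional_nodes(back$region_table)))
  }
  expect_true(all(back$subjects$pct_correct_total >= 0 &
                    back$subjects$pct_correct_total <= 100))
  expect_true(all(back$subjects$age_days > 0))
})

test_that("generated scan ages reproduce the configured group models", {
  cfg <- small_cohort_config(seed = 104, n_per_group = 400, ns = 4, nf = 3,
                             n_timepoints = 50)
  cohort <- generate_cohort(cfg)
  ctrl <- cohort$subjects$age_days[cohort$subjects$group == "control"]
  tg <- cohort$subjects$age_days[cohort$subjects$group == "transgenic"]
  expect_equal(mean(ctrl), 151.11, tolerance = 3 * 12.06 / sqrt(400) / 151)
  # transgenic ages are truncated below 365; allow the induced small bias
  expect_equal(mean(tg), 181, tolerance = 0.03)
  expect_gt(mean(tg), mean(ctrl))  # the study's training-delay confound
})

test_that("time-series generation validates its spec and recovers structure", {
  expect_error(generate_time_series(matrix(c(1, 2, 2, 1), 2), 100),
               "positive definite")
  expect_error(generate_time_series(diag(3), n_timepoints = 2), "few time")

  prec <- diag(6)
  prec[1, 2] <- prec[2, 1] <- -0.6
  ts <- generate_time_series(prec, n_timepoints = 5000, tr_seconds = 2,
                             seed = 9, band_hz = c(0.005, 0.2))
  pc <- partial_correlation_matrix(ts)
  expect_equal(pc[1, 2], 0.6, tolerance = 0.1)

  iid <- generate_time_series(diag(6), n_timepoints = 5000, tr_seconds = 2,
                              seed = 10, band_hz = c(0.005, 0.2))
  pci <- partial_correlation_matrix(iid)
  expect_true(all(abs(pci[upper.tri(pci)]) < 0.05))
})

test_that("planted regional effects are local, recorded and commutative", {
  cohort <- generate_cohort(small_cohort_config(seed = 105, n_per_group = 3))
  nodes <- structural_nodes(cohort$region_table)
  region <- nodes$label[2]

  same <- plant_regional_effect(cohort, region, "mean_fa", delta = 0)
  expect_equal(same$streamlines, cohort$streamlines)
  expect_equal(length(same$manifest$regional_effects), 1)

  shifted <- plant_regional_effect(cohort, region, "mean_fa", delta = -0.5)
  tab <- cohort$region_table
  tg <- cohort$subjects$subject_id[cohort$subjects$group == "transgenic"]
  for (sid in tg) {
    w0 <- build_structural_connectome(
      cohort$streamlines[cohort$streamlines$subject_id == sid, ], tab,
      "fa_weighted")$weights
    w1 <- build_structural_connectome(
      shifted$streamlines[shifted$streamlines$subject_id == sid, ], tab,
      "fa_weighted")$weights
    # only edges incident to the planted region change
    changed <- which(abs(w1 - w0) > 1e-12, arr.ind = TRUE)
    expect_true(all(changed[, 1] == 2 | changed[, 2] == 2))
    expect_lt(sum(w1[2, ]), sum(w0[2, ]))
  }
  # control subjects untouched
  ctrl <- cohort$subjects$subject_id[cohort$subjects$group == "control"]
  expect_equal(shifted$streamlines[shifted$streamlines$subject_id %in% ctrl, ],
               cohort$streamlines[cohort$streamlines$subject_id %in% ctrl, ])

  other <- nodes$label[5]
  ab <- plant_regional_effect(
    plant_regional_effect(cohort, region, "mean_fa", -0.3),
    other, "length_mm", 0.2)
  ba <- plant_regional_effect(
    plant_regional_effect(cohort, other, "length_mm", 0.2),
    region, "mean_fa", -0.3)
  expect_equal(ab$streamlines, ba$streamlines)

  expect_error(plant_regional_effect(cohort, "No such region", "mean_fa", 1),
               "unknown region")
})

test_that("planted effects round-trip through the pipeline statistics", {
  # large effect, moderate n: group difference direction must be recovered
  cfg <- small_cohort_config(seed = 106, n_per_group = 8, fa_effect = 0.3)
  cohort <- generate_cohort(cfg)
  tab <- cohort$region_table
  strengths <- vapply(cohort$subjects$subject_id, function(sid) {
    sl <- cohort$streamlines[cohort$streamlines$subject_id == sid, ]
    conn <- build_structural_connectome(sl, tab, "fa_weighted")
    summarize_connectome(conn)$global$avg_strength
  }, numeric(1))
  grp <- cohort$subjects$group
  expect_gt(mean(strengths[grp == "control"]),
            mean(strengths[grp == "transgenic"]))

  # behavior coupling: the manifest's target correlation has the right sign
  bc <- cohort$manifest$behavior_coupling
  metric_vals <- vapply(cohort$subjects$subject_id, function(sid) {
    sl <- cohort$streamlines[cohort$streamlines$subject_id == sid, ]
    conn <- build_structural_connectome(sl, tab, bc$kind)
    summarize_connectome(conn)$global[[bc$metric]]
  }, numeric(1))
  r <- cor(metric_vals, cohort$subjects[[bc$outcome]], method = "spearman")
  expect_lt(r, 0)  # planted negative coupling
})
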