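make_ts <- function(m, tr = 2) regional_ts(m, tr_seconds = tr)

test_that("preprocessing removes trends and flags constant signals", {
  tt <- 200
  ramp <- matrix(seq_len(tt) * 0.3 + 5, nrow = 1)
  noise <- matrix(rnorm(tt), nrow = 1)
  # a pure ramp detrends to zero -> constant-signal error naming the region
  expect_error(preprocess_series(make_ts(rbind(ramp, noise))),
               "constant.*region")
  ok <- preprocess_series(make_ts(rbind(ramp + rnorm(tt), noise)))
  expect_equal(rowMeans(ok$data), c(0, 0), tolerance = 1e-10)
  expect_equal(apply(ok$data, 1, sd), c(1, 1), tolerance = 1e-10)
  expect_true(all(c("detrend", "bandpass", "zscore") %in% ok$provenance))
})

test_that("band-pass keeps in-band and suppresses out-of-band power", {
  tr <- 2
  tt <- 600
  t_sec <- (seq_len(tt) - 1) * tr
  row <- sin(2 * pi * 0.05 * t_sec) + sin(2 * pi * 0.2 * t_sec)
  pre <- preprocess_series(make_ts(rbind(row, rnorm(tt)), tr = tr),
                           band_hz = c(0.01, 0.1))
  # FFT power-spectrum oracle on the filtered signal
  spec <- Mod(fft(pre$data[1, ]))^2
  freqs <- (seq_len(tt) - 1) / (tt * tr)
  p_in <- sum(spec[abs(freqs - 0.05) < 0.005])
  p_out <- sum(spec[abs(freqs - 0.2) < 0.005])
  expect_lt(p_out, 0.01 * p_in)
})

test_that("band limits are validated against the Nyquist frequency", {
  m <- matrix(rnorm(200), 2)
  expect_error(preprocess_series(make_ts(m), band_hz = c(0.01, 0.3)),
               "Nyquist")
  expect_error(preprocess_series(make_ts(m), band_hz = c(0.1, 0.01)),
               "Nyquist|band")
})

test_that("a nuisance regressor identical to a signal zeroes it out", {
  set.seed(4)
  tt <- 300
  sig <- rnorm(tt)
  m <- rbind(sig, rnorm(tt))
  expect_error(preprocess_series(make_ts(m), nuisance = cbind(sig)),
               "constant")
})

test_that("preprocessing is idempotent on its own output", {
  set.seed(5)
  m <- matrix(rnorm(5 * 400), 5)
  once <- preprocess_series(make_ts(m))
  twice <- preprocess_series(once)
  expect_equal(twice$data, once$data, tolerance = 1e-8)
})

test_that("partial correlation reduces to Pearson for two regions", {
  set.seed(6)
  m <- matrix(rnorm(2 * 500), 2)
  pc <- partial_correlation_matrix(m)
  expect_equal(pc[1, 2], cor(m[1, ], m[2, ]), tolerance = 1e-12)
  expect_equal(diag(pc), c(1, 1))
})

test_that("partial correlation matches the regression-residual definition", {
  set.seed(8)
  tt <- 400
  x1 <- rnorm(tt)
  x2 <- rnorm(tt)
  x3 <- x1 + x2 + rnorm(tt)
  m <- rbind(x1, x2, x3)
  pc <- partial_correlation_matrix(m)
  # independent oracle: correlation of residuals after regressing out the rest
  res_pc <- function(i, j, m) {
    rest <- t(m[-c(i, j), , drop = FALSE])
    cor(stats::lm.fit(cbind(1, rest), m[i, ])$residuals,
        stats::lm.fit(cbind(1, rest), m[j, ])$residuals)
  }
  for (i in 1:2) {
    for (j in (i + 1):3) {
      expect_equal(pc[i, j], res_pc(i, j, m), tolerance = 1e-10)
    }
  }
})

test_that("independent series give near-zero partial correlations", {
  set.seed(9)
  m <- matrix(rnorm(8 * 10000), 8)
  pc <- partial_correlation_matrix(m)
  off <- pc[upper.tri(pc)]
  expect_true(all(abs(off) < 0.05))
})

test_that("singular correlation matrices error without regularization", {
  m <- matrix(rnorm(300), 3)
  m <- rbind(m, m[1, ] * 2)  # exact duplicate direction
  expect_error(partial_correlation_matrix(m, regularize = FALSE),
               "singular|ill-conditioned")
  pc <- partial_correlation_matrix(m, regularize = TRUE)
  expect_true(all(is.finite(pc)))
})

test_that("Fisher z is arctanh with domain checks", {
  expect_equal(fisher_z(0), 0)
  # series oracle: arctanh(r) = sum r^(2k+1)/(2k+1)
  k <- 0:200
  expect_equal(fisher_z(0.5), sum(0.5^(2 * k + 1) / (2 * k + 1)),
               tolerance = 1e-12)
  expect_equal(fisher_z(-0.3), -fisher_z(0.3))
  expect_error(fisher_z(1), "\\|r\\| < 1")
  expect_error(fisher_z(-1.2), "\\|r\\| < 1")
})

test_that("functional connectome excludes negatives and binarizes z > 0", {
  set.seed(10)
  tt <- 400
  nodes <- functional_nodes(make_region_table(ns = 2, nf = 2))
  x <- rnorm(tt)
  anti <- rbind(x + rnorm(tt, sd = 0.3), -x + rnorm(tt, sd = 0.3))
  w_anti <- build_functional_connectome(make_ts(anti), nodes,
                                        "func_weighted")
  expect_equal(sum(w_anti$weights), 0)  # negative correlation -> no edge

  pos <- rbind(x, 0.5 * x + sqrt(1 - 0.25) * rnorm(tt))
  pc <- partial_correlation_matrix(pos)
  w_pos <- build_functional_connectome(make_ts(pos), nodes, "func_weighted")
  expect_equal(w_pos$weights[1, 2], atanh(pc[1, 2]), ignore_attr = TRUE)
  b_pos <- build_functional_connectome(make_ts(pos), nodes, "func_binary")
  expect_equal(unname(b_pos$weights[1, 2]), 1)
})

test_that("binary functional connectome is the indicator of the weighted one", {
  set.seed(12)
  nodes <- functional_nodes(make_region_table(ns = 6, nf = 6))
  m <- matrix(rnorm(6 * 300), 6)
  w <- build_functional_connectome(make_ts(m), nodes, "func_weighted")
  b <- build_functional_connectome(make_ts(m), nodes, "func_binary")
  expect_equal(b$weights, (w$weights > 0) * 1)
  expect_true(all(b$weights %in% c(0, 1)))
})

test_that("block-diagonal planted precision recovers zero between blocks", {
  set.seed(13)
  prec <- diag(8)
  prec[1, 2] <- prec[2, 1] <- -0.4
  prec[5, 6] <- prec[6, 5] <- -0.4
  # wide generation band keeps the effective sample count high
  ts <- generate_time_series(prec, n_timepoints = 5000, tr_seconds = 2,
                             band_hz = c(0.005, 0.2))
  pc <- partial_correlation_matrix(ts)
  expect_gt(pc[1, 2], 0.2)
  expect_gt(pc[5, 6], 0.2)
  expect_true(all(abs(pc[3:4, 5:8]) < 0.05))
})

test_that("regional time series round-trip through TSV with sidecar", {
  ts <- regional_ts(matrix(rnorm(4 * 50), 4), tr_seconds = 2,
                    subject_id = "subXX")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_regional_ts(ts, path)
  back <- read_regional_ts(path)
  expect_equal(back$data, ts$data, tolerance = 1e-12)
  expect_equal(back$tr_seconds, 2)
  expect_equal(back$subject_id, "subXX")
})

test_that("voxel averaging produces regional means", {
  vox <- rbind(c(1, 2), c(3, 4), c(10, 20))
  ts <- average_voxels_by_region(vox, c(1, 1, 2), 2, tr_seconds = 2)
  expect_equal(ts$data, rbind(c(2, 3), c(10, 20)))
  expect_error(average_voxels_by_region(vox, c(1, 1, 3), 2), "1..n_regions")
})
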