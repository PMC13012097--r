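test_that("Hilbert phase advances linearly for a tone and ignores amplitude", {
  fs <- 10
  tt <- (0:1199) / fs
  th <- analytic_phase(cos(2 * pi * 0.03 * tt))
  # unwrapped phase slope ~ 2 pi f / fs in the middle 80%
  d <- diff(th)
  d <- (d + pi) %% (2 * pi) - pi
  mid <- d[120:1080]
  expect_equal(mean(mid), 2 * pi * 0.03 / fs, tolerance = 0.01)
  # sin lags cos by pi/2
  ths <- analytic_phase(sin(2 * pi * 0.03 * tt))
  dphi <- (th - ths + pi) %% (2 * pi) - pi
  expect_equal(median(dphi[120:1080]), pi / 2, tolerance = 0.02)
  # positive scaling leaves the phase untouched
  x <- filter_band(rnorm(1200))
  expect_equal(analytic_phase(5 * x), analytic_phase(x), tolerance = 1e-9)
  expect_true(all(th >= -pi & th < pi))
  expect_error(analytic_phase(rep(0, 100)), "undefined")
})

test_that("phase binning respects the uniform edge convention", {
  expect_equal(discretize_phase(-pi, 8), 0L)
  expect_equal(discretize_phase(pi - 1e-9, 8), 7L)
  expect_equal(discretize_phase(c(-0.1, 0.1), 2), c(0L, 1L))
  # uniform phases occupy all bins evenly
  set.seed(5)
  s <- discretize_phase(runif(8000, -pi, pi - 1e-12), 8)
  freqs <- tabulate(s + 1, 8) / 8000
  expect_true(all(abs(freqs - 0.125) < 0.02))
  expect_error(discretize_phase(0, 1))
})

test_that("plug-in entropy matches closed forms", {
  expect_equal(plugin_entropy(rep(0:7, 100)), 3)
  expect_equal(plugin_entropy(rep(2L, 50)), 0)
  x <- c(0L, 1L, 1L, 0L, 1L)
  expect_equal(plugin_entropy(cbind(x, x)), plugin_entropy(x))
  expect_error(plugin_entropy(integer(0)), "empty")
})

test_that("the one-cycle lag is round(fs / f_center)", {
  expect_identical(default_lag(0.03, 10), 333L)
  expect_identical(default_lag(0.05, 10), 200L)
  expect_identical(default_lag(0.1, 10), 100L)
  expect_error(default_lag(6, 10))
})

test_that("transfer entropy vanishes exactly for constant series", {
  set.seed(2)
  y <- sample(0:7, 500, replace = TRUE)
  con <- rep(3L, 500)
  tp <- phase_te(con, y, lag = 50)
  expect_identical(tp$te_xy, 0)
  tp2 <- phase_te(y, con, lag = 50)
  expect_identical(tp2$te_xy, 0)
  expect_error(phase_te(y, y, lag = 0), "positive")
  expect_error(phase_te(y, y, lag = 500), "smaller")
})

test_that("delta TE is antisymmetric and TE nonnegative on random inputs", {
  set.seed(3)
  for (i in 1:20) {
    n <- sample(50:300, 1)
    nb <- sample(c(2, 4, 8), 1)
    x <- sample(0:(nb - 1), n, replace = TRUE)
    y <- sample(0:(nb - 1), n, replace = TRUE)
    lag <- sample(1:(n %/% 3), 1)
    ab <- phase_te(x, y, lag, nb)
    ba <- phase_te(y, x, lag, nb)
    expect_identical(ab$delta_te, -ba$delta_te)
    expect_identical(ab$te_xy, ba$te_yx)
    expect_gte(ab$te_xy, 0)
    expect_gte(ab$te_yx, 0)
    expect_identical(ab$delta_te, ab$te_xy - ab$te_yx)
    expect_identical(ab$n_samples_used, n - lag)
  }
})

test_that("phase_te equals the brute-force count-table oracle exactly", {
  set.seed(11)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    lag <- sample(1:(n - 2), 1)
    x <- sample(0:1, n, replace = TRUE)
    y <- sample(0:1, n, replace = TRUE)
    o <- te_oracle(x, y, lag)
    tp <- phase_te(x, y, lag, n_bins = 2)
    expect_equal(tp$te_xy, o$te_xy, tolerance = 1e-12)
    expect_equal(tp$te_yx, o$te_yx, tolerance = 1e-12)
  }
  # and for a larger alphabet on longer series
  for (i in 1:5) {
    x <- sample(0:7, 400, replace = TRUE)
    y <- sample(0:7, 400, replace = TRUE)
    o <- te_oracle(x, y, 37)
    tp <- phase_te(x, y, 37, n_bins = 8)
    expect_equal(tp$te_xy, o$te_xy, tolerance = 1e-12)
    expect_equal(tp$te_yx, o$te_yx, tolerance = 1e-12)
  }
})

test_that("a lagged copy process transfers one bit in one direction only", {
  set.seed(13)
  lag <- 333
  x <- sample(0:1, 2048 + lag, replace = TRUE)
  y <- x[1:2048]          # y_t = x_{t - lag} once x is shifted forward
  xs <- x[(lag + 1):(2048 + lag)]
  tp <- phase_te(xs, y, lag, n_bins = 2)
  expect_equal(tp$te_xy, 1, tolerance = 0.05)
  expect_equal(tp$te_yx, 0, tolerance = 0.05)
})

test_that("voxelwise TE maps reduce to phase_te and aggregate linearly", {
  set.seed(17)
  taps <- design_fir()
  n <- 1200
  bold <- filter_band(matrix(rnorm(n * 2), n, 2), taps)
  eeg <- filter_band(matrix(rnorm(n), n, 1), taps)
  h2o <- filter_band(rnorm(n), taps)
  tm <- pairwise_te_map(bold, eeg, h2o, lag = 333, n_bins = 8)
  # single electrode: the map entry equals the direct pair computation
  direct <- phase_te_signals(bold[, 1], eeg[, 1], lag = 333)
  expect_equal(tm$bold_eeg$delta_te[1], direct$delta_te, tolerance = 1e-12)
  expect_equal(tm$bold_eeg$te_fwd[1], direct$te_xy, tolerance = 1e-12)
  # aggregation identities on a 9-label atlas
  mask <- array(TRUE, c(1, 1, 9))
  atlas <- array(1:9, c(1, 1, 9))
  vals <- list(delta_te = rep(2.5, 9), te_fwd = rep(3, 9), te_rev = rep(0.5, 9))
  agg <- aggregate_te(vals, atlas, mask)
  expect_equal(agg$delta_te, rep(2.5, 10))
  # whole brain mean is the voxel-weighted mean of ROI means
  v2 <- list(delta_te = as.numeric(1:9))
  agg2 <- aggregate_te(v2, atlas, mask)
  roi_means <- agg2$delta_te[agg2$roi != "whole_brain"]
  expect_equal(agg2$delta_te[agg2$roi == "whole_brain"],
               weighted.mean(roi_means,
                             agg2$n_voxels[agg2$roi != "whole_brain"]))
  # subtraction commutes with aggregation on a full 9-label atlas
  set.seed(21)
  vals9 <- list(te_fwd = runif(9, 0, 2), te_rev = runif(9, 0, 2))
  vals9$delta_te <- vals9$te_fwd - vals9$te_rev
  agg3 <- aggregate_te(vals9, atlas, mask)
  expect_equal(agg3$delta_te, agg3$te_fwd - agg3$te_rev, tolerance = 1e-12)
})

test_that("cross-correlation lag maps recover constructed shifts", {
  set.seed(19)
  taps <- design_fir()
  s <- filter_band(rnorm(1500), taps)
  n <- 1200
  shift <- 5
  bold <- cbind(s[1:n],                      # the seed itself
                s[(1 + shift):(n + shift)],  # seed delayed by 5 samples
                filter_band(rnorm(n), taps)) # independent voxel
  xl <- xcorr_lag_map(bold, seed_cols = 1, fs = 10, f_center = 0.03)
  expect_equal(xl$lag_s[1], 0)
  expect_equal(xl$lag_s[2], -shift / 10)
  expect_gt(xl$max_corr[1], 0.99)
  expect_error(xcorr_lag_map(cbind(rep(1, 100), rnorm(100)), 1), "flat seed")
})

test_that("lag-vs-TE correlation is null-calibrated on uncoupled voxels", {
  set.seed(23)
  taps <- design_fir()
  n <- 1200
  ps <- replicate(12, {
    bold <- filter_band(matrix(rnorm(n * 12), n, 12), taps)
    te_map <- rnorm(12)
    xl <- xcorr_lag_map(bold, seed_cols = 1:2, fs = 10, te_map = te_map,
                        n_perm = 200, perm_seed = 29)
    xl$te_correlation$p
  })
  expect_gte(mean(ps > 0.05, na.rm = TRUE), 0.75)
})
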