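test_that("cleaning chain preserves constants and removes an isolated spike", {
  x <- rep(100, 300)
  expect_equal(clean_trace(x), x)
  # single large spike against a noisy but tight background: the global
  # MAD rule flags it and interpolation restores the neighbours' level
  set.seed(1)
  x <- 100 + rnorm(300, 0, 1)
  x[150] <- 160
  med <- median(x); sig <- 1.4826 * mad(x, constant = 1)
  expect_gt(abs(x[150] - med), 2 * sig)  # the spike is indeed flagged
  cl <- clean_trace(x)
  cl_ref <- clean_trace(replace(x, 150, (x[149] + x[151]) / 2))
  expect_equal(cl, cl_ref, tolerance = 1e-9)
})

test_that("cleaning is causal up to the 3-sample median lookahead", {
  set.seed(2)
  x <- 120 + cumsum(rnorm(500, 0, 0.1))
  a <- clean_trace(x)
  b <- clean_trace(c(x, 200, 90, 145))  # future samples appended
  n <- length(x)
  expect_equal(a[1:(n - 3)], b[1:(n - 3)], tolerance = 1e-9)
})

test_that("cleaning is idempotent on smooth traces after warm-up", {
  t <- seq(0, 999)
  x <- 150 + 10 * sin(2 * pi * t / 600)
  once <- clean_trace(x)
  twice <- clean_trace(once)
  ref <- clean_trace(once)  # re-application of the filter chain itself
  expect_equal(twice, ref, tolerance = 1e-12)
  # no samples are flagged on the smooth trace, so the only change on a
  # second pass is the deterministic filter re-application
  med <- median(once)
  expect_true(all(abs(once - med) <= 2 * 1.4826 * mad(once, constant = 1)))
})

test_that("baseline subtraction is exact arithmetic", {
  t <- full_grid()
  x <- rep(150, length(t))
  expect_equal(baseline_delta(x, t), rep(0, length(t)))
  # toy: baseline values {140,150,160}, post value 200 -> delta 50
  t2 <- seq(-25 * 60, 60, by = 1)
  x2 <- rep(150, length(t2))
  x2[t2 %in% c(-1500, -1499, -1498)] <- c(140, 150, 160)
  n_base <- sum(t2 >= -1500 & t2 <= 0)
  base_mean <- (140 + 150 + 160 + 150 * (n_base - 3)) / n_base
  x2[length(x2)] <- 200
  dg <- baseline_delta(x2, t2)
  expect_equal(dg[length(dg)], 200 - base_mean, tolerance = 1e-12)
  # baseline mean of the result is exactly zero
  expect_equal(mean(dg[t2 >= -1500 & t2 <= 0]), 0, tolerance = 1e-12)
  expect_error(baseline_delta(x2[1:100], t2[1:100] + 1e5), "outside")
})

test_that("smoothed derivative matches a brute-force diff+boxcar oracle", {
  # linear ramp of 1 mg/dL per second -> 60 mg/dL/min everywhere
  x <- seq(0, 499)
  expect_equal(smoothed_derivative(x), rep(60, 500), tolerance = 1e-9)
  expect_equal(smoothed_derivative(rep(7, 100)), rep(0, 100))
  # piecewise ramp vs an independent elementwise oracle
  y <- c(seq(0, 50, length.out = 200), rep(50, 150),
         seq(50, 10, length.out = 150))
  d_oracle <- c(NA, diff(y)) * 60
  d_oracle[1] <- d_oracle[2]
  sm <- vapply(seq_along(y), function(i)
    mean(d_oracle[max(1, i - 59):i]), 0)
  expect_equal(smoothed_derivative(y), sm, tolerance = 1e-9)
})

test_that("onset: a sustained 10-sigma step at t = 2 min gives theta = 2.0 exactly", {
  set.seed(3)
  t <- seq(-25 * 60, 30 * 60, by = 1)
  noise <- rnorm(length(t), 0, 1)
  x <- 150 + noise
  y0_pre <- x[t < 0] - median(x[t >= -300 & t <= 0])
  sig_y <- 1.4826 * mad(y0_pre, constant = 1)
  x[t >= 120] <- x[t >= 120] + 10 * sig_y
  expect_equal(detect_onset(x, t), 2.0)
})

test_that("onset: ramp from t = 0 with huge slope fires at theta = 0", {
  set.seed(4)
  t <- seq(-25 * 60, 30 * 60, by = 1)
  x <- 150 + rnorm(length(t), 0, 0.5)
  # slope so large that the level condition holds from the first sample
  x[t >= 0] <- x[t >= 0] + 50 * (t[t >= 0] + 1)
  expect_equal(detect_onset(x, t), 0)
})

test_that("onset: white noise alone rarely triggers", {
  set.seed(5)
  hits <- vapply(1:20, function(i) {
    t <- seq(-25 * 60, 30 * 60, by = 1)
    x <- 150 + rnorm(length(t), 0, 2)
    !is.na(detect_onset(x, t))
  }, logical(1))
  expect_lte(mean(hits), 0.05)
})

test_that("excursion metrics follow triangle geometry", {
  t <- full_grid()
  dg <- triangle_dg(t, peak = 200, t_peak = 20, t_end = 40)
  dgdt <- smoothed_derivative(dg)
  m <- excursion_metrics(dg, dgdt, t)
  expect_equal(m$peak_dg, 200, tolerance = 1e-9)
  expect_equal(m$peak_dg_time, 20, tolerance = 1e-3)
  expect_equal(m$half_max_time, 30, tolerance = 0.05)
  expect_equal(m$return_time, 40, tolerance = 0.05)
  # no excursion -> absent metrics with a recorded reason
  m0 <- excursion_metrics(rep(0, length(t)), rep(0, length(t)), t)
  expect_true(is.na(m0$peak_dg))
  expect_match(m0$reason, "no excursion")
})

test_that("ramp-plateau trace: peak derivative and plateau band rule", {
  t <- full_grid()
  tm <- t / 60
  dg <- numeric(length(t))
  dg[tm >= 0 & tm <= 10] <- 5 * tm[tm >= 0 & tm <= 10]   # 5 mg/dL/min
  dg[tm > 10] <- 50
  dgdt <- smoothed_derivative(dg)
  m <- excursion_metrics(dg, dgdt, t)
  expect_equal(m$peak_deriv, 5, tolerance = 0.05)
  # plateau starts once the smoothed derivative enters +/-10% of the rise
  expect_false(anyNA(m$plateau))
  expect_gte(m$plateau[1], 10)
  expect_lt(m$plateau[1], 13)
})

test_that("positive-only iAUC: triangle area, clipping, monotonicity", {
  t <- full_grid()
  dg <- triangle_dg(t, peak = 100, t_peak = 10, t_end = 20)
  expect_equal(iauc_positive(dg, t), 1000, tolerance = 0.5)
  expect_equal(iauc_positive(-abs(dg), t), 0)
  # adding a below-baseline dip leaves the value unchanged
  dip <- dg
  dip[t / 60 > 50 & t / 60 < 70] <- -30
  expect_equal(iauc_positive(dip, t), iauc_positive(dg, t))
  # monotone in the pointwise order
  set.seed(6)
  for (i in 1:5) {
    a <- rnorm(length(t), 0, 10)
    b <- a + abs(rnorm(length(t), 0, 5))
    expect_gte(iauc_positive(b, t), iauc_positive(a, t))
  }
  # agrees with a 1-s Riemann sum within 0.5%
  riemann <- sum(pmax(dg[t >= 0 & t <= 90 * 60], 0)) / 60
  expect_equal(iauc_positive(dg, t), riemann, tolerance = 0.005 * riemann)
})

test_that("onset detection lags true onset by a small positive latency", {
  # the detector waits for the rise to clear its noise thresholds, so it
  # can only fire at or after the true onset, and with these excursion
  # slopes the latency stays under a few minutes
  cfg <- small_cfg(doses = c(1, 2, 2.5))
  coh <- simulate_cohort(cfg, seed = 9)
  err <- vapply(coh, function(s) {
    gm <- glucose_metrics(s)
    gm$theta - s$ground_truth$t_on_min
  }, 0)
  expect_false(anyNA(err))
  expect_true(all(err > -0.5))          # never fires materially early
  expect_lte(median(err), 3)            # bounded detection latency
})
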