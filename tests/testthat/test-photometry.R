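test_that("motion correction removes an exact affine artifact", {
  set.seed(1)
  n <- 2000
  artifact <- cumsum(rnorm(n, 0, 0.1))
  neural <- sin(2 * pi * seq_len(n) / 700)
  sig <- 5 + 1.2 * artifact + neural
  corrected <- motion_correct(sig, artifact)
  # exact identity: residuals of signal ~ reference equal the residuals of
  # neural ~ reference (the affine artifact is annihilated)
  expect_equal(corrected, unname(residuals(lm(neural ~ artifact))),
               tolerance = 1e-9)
  expect_lt(abs(cor(corrected, artifact)), 1e-8)
  # constant reference degenerates to mean subtraction with a warning
  expect_warning(mc <- motion_correct(sig, rep(3, n)), "constant reference")
  expect_equal(mc, sig - mean(sig))
})

test_that("zero-phase low-pass: DC exact, passband preserved, stopband crushed, no phase shift", {
  t <- seq_len(6000)
  slow <- sin(2 * pi * t / 900)       # 15-min period: passband
  fast <- sin(2 * pi * t / 30)        # 30-s period: stopband
  x <- 7 + slow + fast
  y <- glycofp:::lowpass_zerophase(x, period_s = 240, order = 3)
  expect_equal(mean(y), mean(x), tolerance = 1e-3)
  core <- 500:5500                     # away from the edges
  expect_equal(y[core], (7 + slow)[core], tolerance = 0.02)
  # zero phase: cross-correlation of filtered vs clean slow wave peaks at 0
  cc <- ccf(y[core], slow[core], lag.max = 60, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  # constant input is exactly preserved
  expect_equal(glycofp:::lowpass_zerophase(rep(4, 3000), 240, 3),
               rep(4, 3000), tolerance = 1e-9)
})

test_that("baseline z-scoring gives zero mean / unit SD on the baseline", {
  t <- full_grid()
  set.seed(2)
  x <- 3 + 2 * rnorm(length(t))
  z <- zscore_baseline(x, t)
  idx <- t >= -1500 & t <= 0
  expect_equal(mean(z[idx]), 0, tolerance = 1e-12)
  expect_equal(sd(z[idx]), 1, tolerance = 1e-12)
  # affine transforms of the input leave the z-trace unchanged
  z2 <- zscore_baseline(10 - 4 * x, t)
  expect_equal(abs(cor(z, z2)), 1, tolerance = 1e-12)
  expect_error(zscore_baseline(rep(1, length(t)), t), "zero baseline SD")
})

test_that("full chain recovers the neural component from a clean session", {
  # drift-free artifact (motion only): the affine regression is unbiased,
  # so at near-zero noise the processed z-trace matches the z-scored truth
  cfg <- synthetic_config(fp_noise_sd = 0.01, spike_rate_per_hour = 0,
                          bleach_rate = 0, glucose_noise_sd = 0)
  set.seed(4)
  g <- simulate_glucose(2, cfg)
  fp <- simulate_fp(g, 2, cfg, anticipatory_scale = 1)
  t <- glycofp:::session_grid(cfg)
  s <- fp_session("m01", 2, t, fp$fp_signal, fp$fp_reference,
                  as.numeric(g), session_order = 1L)
  Z <- process_fp(s)
  # ground truth pushed through the same deterministic clean + low-pass +
  # z-score chain: the pipeline treats recovered and true neural alike
  truth_z <- zscore_baseline(
    clean_and_lowpass(fp$truth$neural - mean(fp$truth$neural)), t)
  expect_gt(cor(Z, truth_z), 0.99)
})

test_that("response metrics on a hand-built z trace", {
  t <- full_grid()
  tm <- t / 60
  Z <- numeric(length(t))
  # rectangular inhibition of depth 2 from 1 to 5 min, bump of 1.5 at 12 min
  Z[tm >= 1 & tm <= 5] <- -2
  Z[tm >= 11.5 & tm <= 12.5] <- 1.5
  m <- response_metrics(Z, t, t_peak_bg = 20)
  expect_equal(m$peak_z, 1.5)
  expect_equal(m$peak_inhibition, -2)
  expect_gte(m$peak_inhibition_time, 1)
  expect_lte(m$peak_inhibition_time, 5)
  # neg AUC integrates only the negative part: depth 2 for 4 min = -8
  expect_equal(m$neg_auc, -8, tolerance = 0.05)
  # total AUC is the signed sum: -8 + 1.5*1 = -6.5 over [0, end]
  expect_equal(m$total_auc, -6.5, tolerance = 0.1)
  # the 12-min bump lies outside the 0-10 min inhibition window by design
  expect_lt(m$peak_inhibition_time, 10)
})

test_that("sliding band power matches a per-window FFT oracle", {
  set.seed(6)
  x <- rnorm(4000)
  w <- 1200
  band_bins <- 1:3
  bp <- glycofp:::band_power_sliding(x, w, band_bins)
  h <- 0.5 - 0.5 * cos(2 * pi * (0:(w - 1)) / (w - 1))
  scale <- 2 / sum(h^2)
  oracle <- function(s) {
    seg <- x[s:(s + w - 1)]
    X <- fft(h * (seg - mean(seg)))
    mean(scale * Mod(X[band_bins + 1])^2)
  }
  for (s in c(1, 500, 1777, length(x) - w + 1))
    expect_equal(bp[s], oracle(s), tolerance = 1e-9)
  expect_length(bp, length(x) - w + 1)
})

test_that("band-power onset: p-values well-formed; strong band-limited burst detected at its start", {
  cfg <- fp_config(n_pseudo = 100)
  t <- seq(-45 * 60, 90 * 60)
  set.seed(7)
  Z <- rnorm(length(t))
  res <- lf_onset(Z, t, cfg)
  expect_true(all(res$p >= 1 / (cfg$n_pseudo + 1) - 1e-12))
  expect_true(all(res$p <= 1))
  expect_equal(length(res$p), length(res$tau))
  # inject a 16-min-period burst of amplitude 5 over the first 20 min
  # after the event (time-limited, so jittered windows mostly miss it)
  Z2 <- Z
  on <- t >= 0 & t <= 20 * 60
  Z2[on] <- Z2[on] + 5 * sin(2 * pi * t[on] / (16 * 60))
  res2 <- lf_onset(Z2, t, cfg)
  expect_false(is.na(res2$onset))
  # window centred before the burst can still straddle it, so detection may
  # lead the true start by up to half a window but must be near it
  expect_gte(res2$onset, -10)
  expect_lte(res2$onset, 10)
  # band power at the detected bin is in the extreme null tail
  expect_lt(min(res2$p), 0.05)
})

test_that("lf_onset errors name the missing support", {
  cfg <- fp_config()
  t <- seq(-15 * 60, 20 * 60)
  expect_error(lf_onset(rnorm(length(t)), t, cfg), "trace too short")
})

test_that("psd_slope recovers the exponent of synthetic 1/f^k baselines", {
  set.seed(9)
  for (k_true in c(0.5, 1, 1.5)) {
    est <- replicate(6, psd_slope(glycofp:::noise_one_over_f(3000, k_true, 1)))
    expect_equal(median(est), k_true, tolerance = 0.35)
  }
  expect_error(psd_slope(rnorm(100)), "25 min")
})
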