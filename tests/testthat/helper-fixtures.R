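# Shared fixtures: small, fast synthetic configurations and toy traces.

# A session grid long enough for every metric window ([-25, +90] min).
full_grid <- function() seq(-25 * 60, 90 * 60, by = 1)

# Cheap cohort config: fewer subjects, otherwise the study conditions.
small_cfg <- function(...) {
  synthetic_config(n_subjects = 3, ...)
}

# A clean session with known components, bypassing the generator.
toy_session <- function(t = full_grid(), glucose = 150, fp = 1,
                        ref = 1, dose = 0, subject = "s1") {
  n <- length(t)
  fp_session(subject_id = subject, dose = dose, t = t,
             fp_signal = rep_len(fp, n), fp_reference = rep_len(ref, n),
             glucose = rep_len(glucose, n), session_order = 1L)
}

# Triangle glucose excursion: 0 at t=0, peak at t_peak (min), back to 0 at
# t_end (min), 0 elsewhere; on a full session grid.
triangle_dg <- function(t, peak = 200, t_peak = 20, t_end = 40) {
  tm <- t / 60
  up <- tm >= 0 & tm <= t_peak
  dn <- tm > t_peak & tm <= t_end
  dg <- numeric(length(t))
  dg[up] <- peak * tm[up] / t_peak
  dg[dn] <- peak * (t_end - tm[dn]) / (t_end - t_peak)
  dg
}

# Independent brute-force Spearman at one lag (oracle for the fast path).
spearman_oracle <- function(x, y, lag) {
  n <- length(x)
  a <- max(0, lag); b <- min(n, n + lag)
  xw <- x[(a + 1):b]
  yw <- y[(a + 1 - lag):(b - lag)]
  cor(rank(xw), rank(yw))
}

# Early-model traces built directly in z units (no photometry chain):
# scale_i * anticipatory template + optional second-phase bump + noise.
make_z_traces <- function(n_sessions, t, scales = rep(1, n_sessions),
                          bump = NULL, noise_sd = 0, shift_min = 0,
                          cfg = synthetic_config()) {
  antic <- glycofp:::anticipatory_template(t, cfg)
  lapply(seq_len(n_sessions), function(i) {
    a <- if (shift_min != 0)
      approx(t + shift_min * 60, antic, xout = t, rule = 2)$y else antic
    z <- scales[i] * 2.5 * a
    if (!is.null(bump)) z <- z + bump
    z + rnorm(length(t), 0, noise_sd)
  })
}
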