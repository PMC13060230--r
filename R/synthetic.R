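#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the statistical structure the analysis pipeline
#' assumes in paired photometry/glucose sessions: dose-dependent glucose
#' excursions whose rise and fall rates both scale with dose (so recovery
#' time is roughly dose-invariant), an anticipatory, dose-invariant
#' photometry inhibition beginning a few minutes before the gavage event, a
#' second-phase inhibitory component coupled with a lag to the glucose rate
#' of rise, 1/f^k baseline noise, bleaching drift, and motion shared with
#' the isosbestic channel.
#'
#' Amplitude units: photometry is generated in arbitrary units scaled so the
#' baseline noise SD is \code{fp_noise_sd}; with the default
#' \code{fp_noise_sd = 1} the neural amplitudes (\code{anticipatory_depth},
#' \code{second_phase_gain}) read approximately as z-units after the
#' pipeline's baseline z-scoring.
#'
#' @param n_subjects number of animals; each receives every dose once.
#' @param doses g/kg doses; 0 is water.
#' @param t_min,t_max session span, minutes relative to the event.
#' @param glucose_baseline fasted baseline glucose, mg/dL.
#' @param peak_amplitude_per_dose peak \eqn{\Delta G} per unit dose,
#'   mg/dL per (g/kg).
#' @param rise_rate_per_dose maximal rate of rise per unit dose,
#'   (mg/dL/min) per (g/kg).
#' @param fall_rate_per_dose maximal rate of fall per unit dose,
#'   (mg/dL/min) per (g/kg).
#' @param absorption_delay_min mean delay from gavage to the start of the
#'   glucose rise, minutes.
#' @param absorption_jitter_sd SD of the per-session delay jitter, minutes.
#' @param glucose_noise_sd additive sensor noise, mg/dL.
#' @param anticipatory_onset start of the anticipatory photometry
#'   inhibition, minutes (negative = before the event).
#' @param anticipatory_depth depth of the anticipatory inhibition
#'   (baseline-noise SD units; dose-invariant).
#' @param anticipatory_recovery_tau recovery time constant of the
#'   anticipatory component, minutes.
#' @param anticipatory_scale_sd SD of the per-session multiplicative scale
#'   on the anticipatory component (trial-to-trial "state" variability).
#' @param second_phase_gain inhibition per unit positive glucose derivative,
#'   (SD units) per (mg/dL/min).
#' @param second_phase_lag lag of the second-phase inhibition behind the
#'   glucose derivative, minutes (positive = photometry follows).
#' @param fp_noise_k aperiodic 1/f^k exponent of the photometry noise.
#' @param fp_noise_sd SD of the photometry noise, arbitrary units.
#' @param bleach_rate fractional fluorescence decay per hour.
#' @param motion_sd amplitude of the motion artifact shared between
#'   channels, arbitrary units.
#' @param spike_rate_per_hour rate of impulsive artifacts (both modalities).
#' @param spike_amplitude artifact amplitude (mg/dL for glucose; signal
#'   units for photometry).
#' @return A list of class \code{"synthetic_config"}.
#' @export
synthetic_config <- function(n_subjects = 6,
                             doses = c(0, 0.5, 1, 2, 2.5),
                             t_min = -25, t_max = 90,
                             glucose_baseline = 150,
                             peak_amplitude_per_dose = 60,
                             rise_rate_per_dose = 5,
                             fall_rate_per_dose = 2,
                             absorption_delay_min = 3.6,
                             absorption_jitter_sd = 0.5,
                             glucose_noise_sd = 2,
                             anticipatory_onset = -4,
                             anticipatory_depth = 2.5,
                             anticipatory_recovery_tau = 25,
                             anticipatory_scale_sd = 0.25,
                             second_phase_gain = 0.15,
                             second_phase_lag = 5,
                             fp_noise_k = 1,
                             fp_noise_sd = 1,
                             bleach_rate = 0.05,
                             motion_sd = 1.0,
                             spike_rate_per_hour = 4,
                             spike_amplitude = 30) {
  cfg <- as.list(environment())
  stopifnot(all(cfg$doses >= 0), cfg$n_subjects >= 1,
            cfg$peak_amplitude_per_dose >= 0, cfg$rise_rate_per_dose >= 0,
            cfg$fall_rate_per_dose >= 0, cfg$glucose_noise_sd >= 0,
            cfg$fp_noise_sd >= 0, cfg$motion_sd >= 0,
            cfg$anticipatory_depth >= 0, cfg$second_phase_gain >= 0)
  structure(cfg, class = "synthetic_config")
}

session_grid <- function(cfg) seq(cfg$t_min * 60, cfg$t_max * 60, by = 1)

# Noiseless excursion: smooth sin^2 rise whose maximal slope is
# rise_rate_per_dose * dose, peak amplitude peak_amplitude_per_dose * dose,
# then an exponential fall whose initial rate is fall_rate_per_dose * dose.
# Because amplitude and both rates all scale linearly with dose, the rise
# duration and the recovery time constant are dose-invariant.
glucose_excursion <- function(t, dose, cfg, t_on_min) {
  A <- cfg$peak_amplitude_per_dose * dose
  r <- cfg$rise_rate_per_dose * dose
  f <- cfg$fall_rate_per_dose * dose
  out <- list(dg = numeric(length(t)), dgdt = numeric(length(t)))
  if (A <= 0 || r <= 0 || f <= 0) return(out)
  T_r <- pi * A / (2 * r)        # rise duration, min
  T_f <- A / f                   # fall time constant, min
  u <- (t / 60) - t_on_min       # minutes since excursion onset
  rise <- u >= 0 & u <= T_r
  fall <- u > T_r
  out$dg[rise] <- A * sin(pi * u[rise] / (2 * T_r))^2
  out$dgdt[rise] <- A * pi / (2 * T_r) * sin(pi * u[rise] / T_r)
  out$dg[fall] <- A * exp(-(u[fall] - T_r) / T_f)
  out$dgdt[fall] <- -out$dg[fall] / T_f
  out
}

# 1/f^k noise by spectral shaping of white noise, scaled to the target SD.
noise_one_over_f <- function(n, k, sd) {
  if (sd <= 0) return(numeric(n))
  w <- stats::rnorm(n)
  if (k == 0) return(w * sd)
  W <- stats::fft(w)
  f <- c(0, seq_len(n - 1)) / n
  f <- pmin(f, 1 - f)            # two-sided frequency magnitude
  shape <- c(0, f[-1]^(-k / 2))  # kill DC; amplitude ~ f^(-k/2)
  x <- Re(stats::fft(W * shape, inverse = TRUE)) / n
  x / stats::sd(x) * sd
}

add_spikes <- function(x, cfg, amplitude) {
  hours <- length(x) / 3600
  n_sp <- stats::rpois(1, cfg$spike_rate_per_hour * hours)
  if (n_sp > 0) {
    idx <- sample.int(length(x), n_sp)
    x[idx] <- x[idx] + amplitude * sample(c(-1, 1), n_sp, replace = TRUE) *
      stats::runif(n_sp, 0.8, 1.5)
  }
  x
}

#' Simulate an arterial glucose trace
#'
#' Baseline plus a dose-scaled excursion beginning a few minutes after the
#' event, with additive sensor noise and occasional impulsive artifacts.
#' Dose 0 yields baseline plus noise only. Uses the current RNG state; seed
#' before calling for reproducibility.
#'
#' @param dose g/kg.
#' @param cfg a \code{\link{synthetic_config}}.
#' @return Numeric trace (mg/dL) on the session grid, with attribute
#'   \code{"truth"}: the noiseless excursion \code{dg}, its derivative
#'   \code{dgdt} (mg/dL/min) and the onset \code{t_on_min}.
#' @export
simulate_glucose <- function(dose, cfg) {
  t <- session_grid(cfg)
  t_on <- max(0.5, cfg$absorption_delay_min +
                stats::rnorm(1, 0, cfg$absorption_jitter_sd))
  exc <- glucose_excursion(t, dose, cfg, t_on)
  g <- cfg$glucose_baseline + exc$dg +
    stats::rnorm(length(t), 0, cfg$glucose_noise_sd)
  g <- add_spikes(g, cfg, cfg$spike_amplitude)
  attr(g, "truth") <- list(dg = exc$dg, dgdt = exc$dgdt, t_on_min = t_on)
  g
}

# Anticipatory inhibition template: 0 before onset; from onset, a smooth dip
# (1 - exp(-u/tau_on)) * exp(-u/tau_rec), normalized to unit depth. With the
# default onset at -4 min and tau_on = 2.5 min, peak inhibition lands ~+2
# min after the event, matching the observed stimulus-locked response.
anticipatory_template <- function(t, cfg) {
  u <- (t / 60) - cfg$anticipatory_onset
  tau_on <- 2.5
  tau_rec <- cfg$anticipatory_recovery_tau
  g <- ifelse(u > 0, (1 - exp(-u / tau_on)) * exp(-u / tau_rec), 0)
  u_pk <- tau_on * log(1 + tau_rec / tau_on)
  pk <- (1 - exp(-u_pk / tau_on)) * exp(-u_pk / tau_rec)
  -g / pk
}

#' Simulate a two-channel photometry trace
#'
#' \code{fp_signal} = bleaching drift + shared motion + neural component +
#' 1/f^k noise; the neural component is an anticipatory template (onset
#' \code{anticipatory_onset} min, dose-invariant depth, exponential
#' recovery) plus a delayed inhibition proportional to the positive part of
#' the glucose derivative. \code{fp_reference} carries the same drift and
#' motion (affinely) plus independent noise and no neural component, so an
#' affine regression of signal on reference removes the artifacts exactly in
#' the noise-free limit.
#'
#' @param glucose trace from \code{\link{simulate_glucose}} (its
#'   \code{"truth"} attribute supplies the noiseless derivative).
#' @param dose g/kg (unused directly; the dose enters through the glucose
#'   derivative).
#' @param cfg a \code{\link{synthetic_config}}.
#' @param anticipatory_scale per-session multiplicative scale on the
#'   anticipatory component (the generator's "state" variable).
#' @return List with \code{fp_signal}, \code{fp_reference}, and
#'   \code{truth} (neural, anticipatory and second-phase components).
#' @export
simulate_fp <- function(glucose, dose, cfg, anticipatory_scale = 1) {
  t <- session_grid(cfg)
  n <- length(t)
  truth <- attr(glucose, "truth")
  dgdt <- if (!is.null(truth)) truth$dgdt else
    causal_ma(c(0, diff(as.numeric(glucose))) * 60, 60)
  antic <- cfg$anticipatory_depth * anticipatory_scale *
    anticipatory_template(t, cfg)
  lag_s <- round(cfg$second_phase_lag * 60)
  drive <- pmax(dgdt, 0)
  second <- -cfg$second_phase_gain *
    c(numeric(lag_s), drive)[seq_len(n)]
  neural <- antic + second
  drift <- 100 * exp(-cfg$bleach_rate * (t - t[1]) / 3600)
  motion <- if (cfg$motion_sd > 0) {
    m <- causal_ma(stats::rnorm(n), 20)
    m / stats::sd(m) * cfg$motion_sd
  } else numeric(n)
  artifact <- drift + motion
  sig <- 5 + 1.2 * artifact + neural +
    noise_one_over_f(n, cfg$fp_noise_k, cfg$fp_noise_sd)
  ref <- artifact + stats::rnorm(n, 0, 0.05 * cfg$fp_noise_sd)
  sig <- add_spikes(sig, cfg, cfg$spike_amplitude / 10)
  list(fp_signal = sig, fp_reference = ref,
       truth = list(neural = neural, anticipatory = antic,
                    second_phase = second))
}

#' Simulate a cohort of sessions
#'
#' Generates \code{n_subjects} animals, each receiving every dose once in a
#' randomized order (recorded as \code{session_order}). Identical
#' \code{(cfg, seed)} reproduces the identical cohort.
#'
#' @param cfg a \code{\link{synthetic_config}}.
#' @param seed integer RNG seed.
#' @return List of \code{\link{fp_session}} objects, each carrying a
#'   \code{ground_truth} list (noiseless glucose excursion, derivative,
#'   onset, neural components, anticipatory scale).
#' @export
simulate_cohort <- function(cfg, seed = 1) {
  set.seed(seed)
  t <- session_grid(cfg)
  out <- list()
  for (subj in seq_len(cfg$n_subjects)) {
    order_idx <- sample(seq_along(cfg$doses))
    for (k in seq_along(order_idx)) {
      dose <- cfg$doses[order_idx[k]]
      scale <- max(0.1, 1 + stats::rnorm(1, 0, cfg$anticipatory_scale_sd))
      g <- simulate_glucose(dose, cfg)
      fp <- simulate_fp(g, dose, cfg, anticipatory_scale = scale)
      gt <- c(attr(g, "truth"), fp$truth,
              list(anticipatory_scale = scale))
      out[[length(out) + 1L]] <- fp_session(
        subject_id = sprintf("m%02d", subj), dose = dose, t = t,
        fp_signal = fp$fp_signal, fp_reference = fp$fp_reference,
        glucose = as.numeric(g), session_order = k, ground_truth = gt)
    }
  }
  out
}
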