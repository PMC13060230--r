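#' Cleaning configuration for 1 Hz traces
#'
#' @param mad_k robust despiking threshold: samples with
#'   \eqn{|y - median| > k \cdot 1.4826 \cdot MAD} (global median/MAD over
#'   the trace) are replaced by linear interpolation.
#' @param median_window centered median filter width, samples (odd).
#' @param causal_ma_window causal moving-average width, samples.
#' @return List of class \code{"clean_config"}.
#' @export
clean_config <- function(mad_k = 2.0, median_window = 7,
                         causal_ma_window = 60) {
  stopifnot(median_window %% 2 == 1, median_window >= 1,
            causal_ma_window >= 1, mad_k > 0)
  structure(list(mad_k = mad_k, median_window = median_window,
                 causal_ma_window = causal_ma_window),
            class = "clean_config")
}

#' Clean a 1 Hz trace
#'
#' Three-stage artifact removal that preserves timing: (1) robust MAD
#' despiking — samples beyond \code{mad_k} robust SDs from the global median
#' are replaced by linear interpolation between the nearest unflagged
#' neighbours; (2) centered median filter; (3) causal moving average with an
#' expanding warm-up window (output at index i averages the most recent
#' \code{min(i, w)} samples), so responses stay stimulus-aligned.
#'
#' @param raw numeric 1 Hz series.
#' @param cfg a \code{\link{clean_config}}.
#' @return Cleaned series, same length.
#' @export
clean_trace <- function(raw, cfg = clean_config()) {
  stopifnot(length(raw) >= cfg$causal_ma_window)
  med <- stats::median(raw)
  sigma <- mad_sigma(raw)
  flagged <- abs(raw - med) > cfg$mad_k * sigma
  if (all(flagged)) stop("all samples flagged as outliers; trace unusable")
  x <- interp_flagged(raw, flagged)
  if (cfg$median_window > 1)
    x <- stats::runmed(x, cfg$median_window, endrule = "median")
  causal_ma(as.numeric(x), cfg$causal_ma_window)
}

#' Baseline-subtracted glucose
#'
#' \eqn{\Delta G(t) = G(t) - mean(G)} over the pre-event baseline window, so
#' amplitudes are comparable across sessions.
#'
#' @param clean cleaned series.
#' @param t time axis, seconds relative to the event.
#' @param baseline_window baseline window in minutes, default
#'   \code{c(-25, 0)}.
#' @return \eqn{\Delta G} series, mg/dL.
#' @export
baseline_delta <- function(clean, t, baseline_window = c(-25, 0)) {
  idx <- which_window(t, baseline_window[1] * 60, baseline_window[2] * 60)
  if (length(idx) == 0 || min(t) > baseline_window[1] * 60 ||
      max(t) < baseline_window[2] * 60)
    stop(sprintf("baseline window [%g, %g] min outside trace support",
                 baseline_window[1], baseline_window[2]))
  clean - mean(clean[idx])
}

#' Smoothed finite-difference derivative
#'
#' Per-second forward difference assigned to the later sample (causal),
#' converted to per-minute units, then smoothed with the causal moving
#' average.
#'
#' @param series 1 Hz series.
#' @param cfg a \code{\link{clean_config}} (only \code{causal_ma_window} is
#'   used).
#' @return Derivative series, units per minute, same length.
#' @export
smoothed_derivative <- function(series, cfg = clean_config()) {
  stopifnot(length(series) >= 2)
  d <- c(NA, diff(series)) * 60
  d[1] <- d[2]
  causal_ma(d, cfg$causal_ma_window)
}

#' Onset detection configuration
#'
#' @param z_mult slope threshold multiplier (threshold
#'   \eqn{T_{slope} = m_d + z \hat\sigma_d}).
#' @param level_mult level threshold multiplier (\eqn{T_{level} = 3
#'   \hat\sigma_y}).
#' @param sustain consecutive samples required, default 60 (1 min at 1 Hz).
#' @param boxcar causal boxcar width for the onset-specific smoothing,
#'   samples (2 min at 1 Hz).
#' @param onset_baseline_window window (minutes) whose median defines the
#'   onset-local baseline.
#' @return List of class \code{"onset_config"}.
#' @export
onset_config <- function(z_mult = 3, level_mult = 3, sustain = 60,
                         boxcar = 120, onset_baseline_window = c(-5, 0)) {
  stopifnot(sustain >= 1, z_mult > 0, level_mult > 0, boxcar >= 1)
  structure(list(z_mult = z_mult, level_mult = level_mult,
                 sustain = sustain, boxcar = boxcar,
                 onset_baseline_window = onset_baseline_window),
            class = "onset_config")
}

#' Detect the first sustained glucose rise
#'
#' Tests two independent conditions against robust baseline-derived
#' thresholds and requires a continuous 1-min run of evidence. Let
#' \eqn{y_0(t)} be the cleaned trace minus the median over the onset
#' baseline window. The slope condition compares the finite-difference
#' derivative of the 2-min causal-boxcar-smoothed \eqn{y_0} with
#' \eqn{T_{slope} = m_d + z \hat\sigma_d} (median and scaled MAD of the
#' baseline derivative); the level condition compares \eqn{y_0} itself with
#' \eqn{T_{level} = 3 \hat\sigma_y} (scaled MAD of baseline \eqn{y_0}).
#' Samples at \eqn{t \ge 0} where either condition holds are marked; the
#' onset \eqn{\theta} is the first sample of the first run of at least
#' \code{sustain} consecutive marked samples.
#'
#' @param clean cleaned series.
#' @param t time axis, seconds relative to the event.
#' @param cfg an \code{\link{onset_config}}.
#' @return Onset time in minutes, or \code{NA} if no sustained rise.
#' @export
detect_onset <- function(clean, t, cfg = onset_config()) {
  pre <- t < 0
  if (!any(pre)) stop("no baseline segment (t < 0) present")
  bw <- cfg$onset_baseline_window * 60
  bidx <- which_window(t, bw[1], bw[2])
  y0 <- clean - stats::median(clean[bidx])
  y0_s <- causal_ma(y0, cfg$boxcar)
  d <- c(NA, diff(y0_s))
  d[1] <- d[2]
  d_pre <- d[pre]
  md <- stats::median(d_pre)
  sig_d <- mad_sigma(d_pre)
  sig_y <- mad_sigma(y0[pre])
  eps <- .Machine$double.eps * max(1, abs(mean(clean)))
  if (sig_d == 0) { warning("degenerate baseline: MAD of derivative is 0")
    sig_d <- eps }
  if (sig_y == 0) { warning("degenerate baseline: MAD of level is 0")
    sig_y <- eps }
  post <- which(t >= 0)
  mark <- d[post] > md + cfg$z_mult * sig_d |
    y0[post] > cfg$level_mult * sig_y
  start <- first_sustained_run(mark, cfg$sustain)
  if (is.na(start)) return(NA_real_)
  t[post[start]] / 60
}

#' Glucose excursion metrics
#'
#' Summarises one excursion: peak \eqn{\Delta G} (value and time) within
#' 0-90 min; peak derivative within 0-30 min; half-max recovery time (first
#' post-peak crossing of half the peak, linear interpolation on the
#' unsmoothed-by-this-function \eqn{\Delta G} series); plateau (first
#' sustained interval where the smoothed derivative sits inside a near-zero
#' band scaled to the preceding peak rise); and return to baseline (first
#' \eqn{\Delta G \le 0} after the peak, else the first sustained relaxation
#' of the derivative back above zero).
#'
#' @param dg \eqn{\Delta G} series, mg/dL.
#' @param dgdt smoothed derivative series, mg/dL/min.
#' @param t time axis, seconds relative to the event.
#' @param peak_window,deriv_window search windows, minutes.
#' @param plateau_band_frac plateau band half-width as a fraction of the
#'   peak rise rate.
#' @param plateau_sustain,relax_sustain consecutive samples required for the
#'   plateau and the relaxation fallback.
#' @return List: \code{peak_dg}, \code{peak_dg_time}, \code{peak_deriv},
#'   \code{peak_deriv_time}, \code{half_max_time}, \code{plateau}
#'   (2-vector, minutes, or NA), \code{return_time} (all times in minutes;
#'   \code{NA} where undefined), and \code{reason} when metrics are absent.
#' @export
excursion_metrics <- function(dg, dgdt, t, peak_window = c(0, 90),
                              deriv_window = c(0, 30),
                              plateau_band_frac = 0.1,
                              plateau_sustain = 60, relax_sustain = 60) {
  if (max(t) < peak_window[2] * 60)
    stop("trace does not span the peak search window")
  out <- list(peak_dg = NA_real_, peak_dg_time = NA_real_,
              peak_deriv = NA_real_, peak_deriv_time = NA_real_,
              half_max_time = NA_real_, plateau = c(NA_real_, NA_real_),
              return_time = NA_real_, reason = NA_character_)
  pw <- which_window(t, peak_window[1] * 60, peak_window[2] * 60)
  if (max(dg[pw]) <= 0) {
    out$reason <- "no excursion above baseline"
    return(out)
  }
  ipk <- pw[which.max(dg[pw])]
  out$peak_dg <- dg[ipk]
  out$peak_dg_time <- t[ipk] / 60
  dw <- which_window(t, deriv_window[1] * 60, deriv_window[2] * 60)
  idv <- dw[which.max(dgdt[dw])]
  out$peak_deriv <- dgdt[idv]
  out$peak_deriv_time <- t[idv] / 60
  # half-max recovery: first crossing of 0.5 * peak after the peak
  half <- 0.5 * out$peak_dg
  post <- seq(ipk, length(dg))
  below <- which(dg[post] <= half)
  if (length(below) > 0) {
    j <- post[below[1]]
    if (j > ipk && dg[j - 1] > half) {
      frac <- (dg[j - 1] - half) / (dg[j - 1] - dg[j])
      out$half_max_time <- (t[j - 1] + frac * (t[j] - t[j - 1])) / 60
    } else out$half_max_time <- t[j] / 60
  }
  # plateau: after the peak rise, |dG/dt| inside the near-zero band
  band <- plateau_band_frac * out$peak_deriv
  after <- seq(idv, length(dg))
  inband <- abs(dgdt[after]) <= band
  st <- first_sustained_run(inband, plateau_sustain)
  if (!is.na(st)) {
    r <- rle(inband)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    k <- which(r$values & r$lengths >= plateau_sustain)[1]
    out$plateau <- c(t[after[starts[k]]], t[after[ends[k]]]) / 60
  }
  # return to baseline: amplitude rule, else sustained derivative relaxation
  ret <- which(dg[post] <= 0)
  if (length(ret) > 0) {
    out$return_time <- t[post[ret[1]]] / 60
  } else {
    relax <- dgdt[post] > 0
    st <- first_sustained_run(relax, relax_sustain)
    if (!is.na(st)) out$return_time <- t[post[st]] / 60
  }
  out
}

#' Positive-only incremental area under the curve
#'
#' Trapezoidal integral of \eqn{\max(\Delta G, 0)} over the window, so only
#' excursions above baseline contribute.
#'
#' @param dg \eqn{\Delta G} series, mg/dL.
#' @param t time axis, seconds.
#' @param window window in minutes, default \code{c(0, 90)}.
#' @return iAUC in mg/dL*min (non-negative).
#' @export
iauc_positive <- function(dg, t, window = c(0, 90)) {
  idx <- which_window(t, window[1] * 60, window[2] * 60)
  trapz(t[idx] / 60, pmax(dg[idx], 0))
}

#' Full glucose metric set for one session
#'
#' Runs the cleaning chain, baseline subtraction, derivative, onset
#' detection, excursion metrics and iAUC for one session.
#'
#' @param session an \code{\link{fp_session}}.
#' @param clean_cfg a \code{\link{clean_config}}.
#' @param onset_cfg an \code{\link{onset_config}}.
#' @return List with the cleaned traces (\code{clean}, \code{dg},
#'   \code{dgdt}) and the scalar metrics (\code{theta} plus all
#'   \code{\link{excursion_metrics}} fields and \code{iauc}).
#' @export
glucose_metrics <- function(session, clean_cfg = clean_config(),
                            onset_cfg = onset_config()) {
  cl <- clean_trace(session$glucose, clean_cfg)
  dg <- baseline_delta(cl, session$t)
  dgdt <- smoothed_derivative(cl, clean_cfg)
  exc <- excursion_metrics(dg, dgdt, session$t)
  c(list(clean = cl, dg = dg, dgdt = dgdt,
         theta = detect_onset(cl, session$t, onset_cfg),
         iauc = iauc_positive(dg, session$t)),
    exc)
}
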