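#' Photometry analysis configuration
#'
#' @param mad_k,median_window,causal_ma_window despiking/cleaning chain, as
#'   in \code{\link{clean_config}}.
#' @param lowpass_period Butterworth low-pass cutoff, expressed as a period
#'   in minutes.
#' @param lowpass_order Butterworth order.
#' @param baseline_window baseline z-scoring window, minutes.
#' @param peak_z_window window for the maximal z deflection, minutes.
#' @param inhibition_window window for peak inhibition (minimum z), minutes.
#' @param band spectral band of interest, as periods in minutes
#'   (\code{c(14, 20)} = frequencies 1/20 to 1/14 cycles per minute).
#' @param spec_window spectrogram window, minutes.
#' @param spec_overlap spectrogram window overlap fraction.
#' @param n_pseudo number of jittered pseudo-events for the band-power null.
#' @param guard exclusion zone around the true event for pseudo-events,
#'   minutes.
#' @param detect_window onset detection window around the event, minutes.
#' @param alpha significance level for the band-power onset.
#' @return List of class \code{"fp_config"}.
#' @export
fp_config <- function(mad_k = 2.0, median_window = 7, causal_ma_window = 60,
                      lowpass_period = 4, lowpass_order = 3,
                      baseline_window = c(-25, 0),
                      peak_z_window = c(0, 15),
                      inhibition_window = c(0, 10),
                      band = c(14, 20), spec_window = 20,
                      spec_overlap = 0.99, n_pseudo = 200, guard = 5,
                      detect_window = c(-10, 10), alpha = 0.05) {
  stopifnot(spec_overlap >= 0, spec_overlap < 1, band[1] < band[2],
            lowpass_period > 0, spec_window > 0)
  structure(as.list(environment()), class = "fp_config")
}

#' Remove shared motion and bleaching via the isosbestic reference
#'
#' Least-squares affine regression of the signal channel on the reference
#' (\code{signal ~ a + b * reference}); the fitted component is subtracted,
#' leaving a zero-mean corrected trace. A constant reference degenerates to
#' mean subtraction (with a warning).
#'
#' @param signal calcium-dependent channel.
#' @param reference isosbestic channel.
#' @return Corrected series (regression residuals).
#' @export
motion_correct <- function(signal, reference) {
  stopifnot(length(signal) == length(reference), length(signal) >= 10)
  if (stats::sd(reference) < .Machine$double.eps * max(1, abs(mean(reference)))) {
    warning("constant reference: motion correction degenerates to mean subtraction")
    return(signal - mean(signal))
  }
  stats::lm.fit(cbind(1, reference), signal)$residuals
}

# Zero-phase Butterworth low-pass with odd-reflection edge padding. The mean
# is removed before filtering and restored after, so DC is preserved exactly
# and edge transients act only on the zero-mean part.
lowpass_zerophase <- function(x, period_s, order) {
  n <- length(x)
  wn <- (1 / period_s) / 0.5          # normalized cutoff (Nyquist = 0.5 Hz)
  bf <- signal::butter(order, wn, type = "low")
  pad <- min(n - 1L, 3L * ceiling(period_s))
  if (n < 3L * pad / 2) stop("trace too short for the low-pass filter padding")
  m <- mean(x)
  xc <- x - m
  ext <- c(2 * xc[1] - xc[(pad + 1L):2L], xc,
           2 * xc[n] - xc[(n - 1L):(n - pad)])
  y <- signal::filter(bf, ext)
  y <- rev(as.numeric(signal::filter(bf, rev(as.numeric(y)))))
  m + y[(pad + 1L):(pad + n)]
}

#' Clean and low-pass a motion-corrected photometry trace
#'
#' The despike/median/causal-MA chain of \code{\link{clean_trace}}, followed
#' by a zero-phase (forward-backward) Butterworth low-pass defined by period
#' (default cutoff 4 min, order 3) to emphasise slow, stimulus-evoked
#' structure.
#'
#' @param corrected motion-corrected series.
#' @param cfg an \code{\link{fp_config}}.
#' @return Filtered series, same length.
#' @export
clean_and_lowpass <- function(corrected, cfg = fp_config()) {
  x <- clean_trace(corrected, clean_config(cfg$mad_k, cfg$median_window,
                                           cfg$causal_ma_window))
  lowpass_zerophase(x, cfg$lowpass_period * 60, cfg$lowpass_order)
}

#' Baseline z-scoring
#'
#' \eqn{Z(t) = (x(t) - \mu_b) / \sigma_b} with mean and SD taken over the
#' pre-event baseline window, yielding a trace with baseline mean 0 and unit
#' SD, comparable across animals.
#'
#' @param filtered filtered series.
#' @param t time axis, seconds.
#' @param baseline_window minutes, default \code{c(-25, 0)}.
#' @return Z-scored series.
#' @export
zscore_baseline <- function(filtered, t, baseline_window = c(-25, 0)) {
  idx <- which_window(t, baseline_window[1] * 60, baseline_window[2] * 60)
  if (length(idx) < 2) stop("baseline window outside trace support")
  mu <- mean(filtered[idx])
  sd_b <- stats::sd(filtered[idx])
  if (sd_b == 0) stop("zero baseline SD: cannot z-score")
  (filtered - mu) / sd_b
}

#' Full photometry processing chain
#'
#' Motion correction on the raw channels, then cleaning and zero-phase
#' low-pass, then baseline z-scoring.
#'
#' @param session an \code{\link{fp_session}}.
#' @param cfg an \code{\link{fp_config}}.
#' @return Z-scored photometry series \eqn{Z_{FP}(t)} on the session grid.
#' @export
process_fp <- function(session, cfg = fp_config()) {
  corrected <- motion_correct(session$fp_signal, session$fp_reference)
  filt <- clean_and_lowpass(corrected, cfg)
  zscore_baseline(filt, session$t, cfg$baseline_window)
}

#' Scalar photometry response metrics
#'
#' Peak z in the early window (0-15 min); peak inhibition (minimum z) in
#' the 0-10 min window with its time; negative AUC — the trapezoidal
#' integral of \eqn{\min(Z, 0)} from the event to the time of peak blood
#' glucose (values above baseline set to 0, so the integral reflects only
#' negative deflections); and the total AUC of the unmodified trace from
#' the event to the end of the session.
#'
#' @param Z z-scored trace.
#' @param t time axis, seconds.
#' @param t_peak_bg time of peak blood glucose, minutes (or \code{NA}).
#' @param cfg an \code{\link{fp_config}}.
#' @return List: \code{peak_z}, \code{peak_inhibition},
#'   \code{peak_inhibition_time} (min), \code{neg_auc} (z*min, <= 0),
#'   \code{total_auc} (z*min).
#' @export
response_metrics <- function(Z, t, t_peak_bg = NA, cfg = fp_config()) {
  pz <- which_window(t, cfg$peak_z_window[1] * 60, cfg$peak_z_window[2] * 60)
  iw <- which_window(t, cfg$inhibition_window[1] * 60,
                     cfg$inhibition_window[2] * 60)
  imin <- iw[which.min(Z[iw])]
  neg_auc <- NA_real_
  if (!is.na(t_peak_bg)) {
    aw <- which_window(t, 0, t_peak_bg * 60)
    neg_auc <- trapz(t[aw] / 60, pmin(Z[aw], 0))
  }
  tw <- which(t >= 0)
  list(peak_z = max(Z[pz]),
       peak_inhibition = Z[imin],
       peak_inhibition_time = t[imin] / 60,
       neg_auc = neg_auc,
       total_auc = trapz(t[tw] / 60, Z[tw]))
}

# Band-limited spectrogram power at every admissible window start, in one
# pass: for each FFT bin in the band, the windowed DFT over a sliding
# segment is a finite-impulse-response filter, so stats::filter computes it
# for all starts at once; per-segment demeaning enters through a running
# mean. Returns bp[s] = band-averaged one-sided PSD of the w-sample segment
# starting at index s.
band_power_sliding <- function(x, w, band_bins) {
  n <- length(x)
  h <- 0.5 - 0.5 * cos(2 * pi * (0:(w - 1)) / (w - 1))  # Hann
  scale <- 2 / sum(h^2)                                  # fs = 1 Hz
  cs <- c(0, cumsum(x))
  segmean <- (cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w
  bp <- 0
  for (k in band_bins) {
    v <- h * exp(-2i * pi * k * (0:(w - 1)) / w)
    cv <- sum(v)
    re <- stats::filter(x, rev(Re(v)), sides = 1)[w:n]
    im <- stats::filter(x, rev(Im(v)), sides = 1)[w:n]
    X <- complex(real = re, imaginary = im) - segmean * cv
    bp <- bp + scale * Mod(X)^2
  }
  bp / length(band_bins)
}

#' Low-frequency band-power onset with a jittered pseudo-event null
#'
#' Computes a sliding-window spectrogram of the z-scored trace (default
#' 20-min Hann windows with 99% overlap), averages PSD over the band of
#' periods 14-20 min, and compares the band power at each time bin
#' \eqn{\tau} relative to the event against the same quantity computed at
#' \code{n_pseudo} pseudo-event times (drawn uniformly without replacement
#' from all admissible times at least \code{guard} minutes from the true
#' event, with full window support). The upper-tailed rank p-value is
#' \eqn{p(\tau) = (1 + \#\{P_{null} \ge P_{real}\}) / (N + 1)}; the onset is
#' the first \eqn{\tau} in the detection window with \eqn{p < \alpha}.
#'
#' @param Z z-scored trace.
#' @param t time axis, seconds relative to the event.
#' @param cfg an \code{\link{fp_config}}.
#' @return List: \code{onset} (minutes, or \code{NA}), \code{tau} (bin
#'   centers, minutes), \code{p} (p-value per bin), \code{p_real} (band
#'   power per bin).
#' @export
lf_onset <- function(Z, t, cfg = fp_config()) {
  w <- cfg$spec_window * 60
  hop <- max(1L, round(w * (1 - cfg$spec_overlap)))
  half <- floor(w / 2)
  n <- length(Z)
  tau <- seq(cfg$detect_window[1] * 60, cfg$detect_window[2] * 60, by = hop)
  # frequencies k/w Hz inside [1/(band_max*60), 1/(band_min*60)] Hz
  f_lo <- 1 / (cfg$band[2] * 60)
  f_hi <- 1 / (cfg$band[1] * 60)
  band_bins <- which((seq_len(half) / w) >= f_lo - 1e-12 &
                       (seq_len(half) / w) <= f_hi + 1e-12)
  if (length(band_bins) == 0) stop("no FFT bins inside the requested band")
  bp <- band_power_sliding(Z, w, band_bins)
  # segment starting at index s covers t[s] .. t[s + w - 1]; the window
  # centered at event time e and offset tau starts at e + tau - half
  start_idx <- function(e) round(e + tau - half - t[1]) + 1L
  ok_event <- function(e) {
    si <- start_idx(e)
    all(si >= 1L & si + w - 1L <= n)
  }
  if (!ok_event(0))
    stop(sprintf(
      "trace too short: need support [%g, %g] s around the event",
      tau[1] - half, tau[length(tau)] + half))
  p_real <- bp[start_idx(0)]
  e_all <- t[1]:t[n]
  admissible <- e_all[abs(e_all) >= cfg$guard * 60 &
                        (e_all + tau[1] - half) >= t[1] &
                        (e_all + tau[length(tau)] + half - 1) <= t[n]]
  if (length(admissible) < cfg$n_pseudo)
    stop(sprintf(
      "only %d admissible pseudo-event times (< n_pseudo = %d); need a span of at least %g s outside the %g-min guard",
      length(admissible), cfg$n_pseudo,
      cfg$n_pseudo + diff(range(tau)) + w, cfg$guard))
  ev <- sample(admissible, cfg$n_pseudo)
  null_mat <- vapply(ev, function(e) bp[start_idx(e)], numeric(length(tau)))
  exceed <- rowSums(null_mat >= p_real)
  p <- (1 + exceed) / (cfg$n_pseudo + 1)
  hit <- which(p < cfg$alpha)
  list(onset = if (length(hit) == 0) NA_real_ else tau[hit[1]] / 60,
       tau = tau / 60, p = p, p_real = p_real)
}

# Welch power spectral density: Hann-windowed, per-segment demeaned,
# overlapping segments, one-sided, fs = 1 Hz.
welch_psd <- function(x, seg_len, overlap = 0.5) {
  n <- length(x)
  seg_len <- min(seg_len, n)
  hop <- max(1L, round(seg_len * (1 - overlap)))
  starts <- seq(1L, n - seg_len + 1L, by = hop)
  h <- 0.5 - 0.5 * cos(2 * pi * (0:(seg_len - 1)) / (seg_len - 1))
  scale <- 2 / sum(h^2)
  half <- floor(seg_len / 2)
  acc <- numeric(half)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1)]
    X <- stats::fft(h * (seg - mean(seg)))
    acc <- acc + scale * Mod(X[2:(half + 1)])^2
  }
  list(freq = seq_len(half) / seg_len, psd = acc / length(starts))
}

#' Aperiodic 1/f^k exponent of the baseline power spectrum
#'
#' Welch PSD over the baseline segment (8-min Hann segments, 50% overlap),
#' then an ordinary least-squares fit of log PSD against log frequency over
#' the fit band; \eqn{k} is minus the slope. Higher \eqn{k} means a greater
#' bias toward slow baseline structure.
#'
#' @param z_baseline baseline segment of the z-scored trace (>= 25 min).
#' @param fit_band frequency band for the log-log fit, Hz; default
#'   \code{c(1/600, 1/60)} (periods 1-10 min).
#' @param seg_len_s Welch segment length, seconds.
#' @return The exponent \eqn{k} (unitless).
#' @export
psd_slope <- function(z_baseline, fit_band = c(1 / 600, 1 / 60),
                      seg_len_s = 480) {
  if (length(z_baseline) < 1500)
    stop("baseline segment must span at least 25 min at 1 Hz")
  wp <- welch_psd(z_baseline, seg_len_s)
  sel <- wp$freq >= fit_band[1] - 1e-12 & wp$freq <= fit_band[2] + 1e-12
  if (sum(sel) < 5)
    stop(sprintf("only %d frequency bins in the fit band (need >= 5)",
                 sum(sel)))
  fit <- stats::lm.fit(cbind(1, log10(wp$freq[sel])), log10(wp$psd[sel]))
  -unname(fit$coefficients[2])
}
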