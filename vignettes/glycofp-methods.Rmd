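---
title: "Methods: paired photometry-glucose analysis in glycofp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired photometry-glucose analysis in glycofp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 4)
library(glycofp)
```

`glycofp` analyses sessions in which a fiber-photometry calcium signal
(plus an isosbestic reference channel) and arterial glucose are recorded
together at 1 Hz around an oral gavage at `t = 0`. This vignette states
the models and the numerical choices precisely, describes what the
synthetic generator does and does not emulate, and lists known
limitations.

## Data model

An `fp_session` holds four equal-length series on a strictly increasing
1-second grid in seconds relative to the event: `fp_signal` (calcium
channel, arbitrary units), `fp_reference` (isosbestic channel),
`glucose` (mg/dL), plus subject, dose (g/kg; 0 = water) and the
within-subject session order. `align_streams()` places raw streams with
their own clocks onto this grid by linear interpolation; at least 115
minutes of common support around the event are required (1-s slack so a
sub-second clock offset does not disqualify a session). Interior gaps of
up to 5 s in loaded files are linearly interpolated with a warning;
longer gaps are an error.

## Glucose pipeline

**Cleaning** (`clean_trace`) is three causal-timing-preserving stages:

1. *Global MAD despiking.* Samples with
   $|y - \mathrm{median}(y)| > k \cdot 1.4826 \cdot \mathrm{MAD}(y)$
   (defaults: $k = 2.0$, median/MAD over the whole trace) are replaced
   by linear interpolation between the nearest unflagged neighbours.
2. *Centered median filter,* width 7 samples.
3. *Causal moving average,* width 60 samples, with an expanding warm-up
   (the output at sample $i$ averages the most recent $\min(i, 60)$
   samples) so the trace keeps its length and its stimulus alignment.

A known behaviour of the *global* threshold: on traces whose excursion
is very large relative to noise, the top of the excursion itself can
exceed the global band and be shaved slightly. We keep the global rule
because it is simple, parameter-free beyond $k$, and the shaving is
immaterial at physiological noise levels; analyses that require exact
peak amplitudes at near-zero noise should be read with this in mind.

**Baseline and derivative.** $\Delta G(t)$ subtracts the mean of the
cleaned trace over $[-25, 0]$ min. The derivative is the per-second
forward difference (assigned to the later sample), converted to
mg/dL/min, then smoothed with the same causal moving average.

**Onset detection** (`detect_onset`). Let $y_0$ be the cleaned trace
minus the *median* over $[-5, 0]$ min. Two conditions are tested at
$t \ge 0$:

* *slope*: the finite-difference derivative of the 2-min causal-boxcar
  smoothed $y_0$ exceeds $m_d + 3\hat\sigma_d$ (median and scaled MAD of
  the baseline derivative);
* *level*: the **unsmoothed** $y_0$ exceeds $3\hat\sigma_y$ (scaled MAD
  of baseline $y_0$). Using the unsmoothed series here is deliberate: a
  step at $t_0$ then yields $\theta = t_0$ exactly, rather than being
  delayed by the boxcar.

The onset $\theta$ is the first sample of the first run of at least 60
consecutive seconds where either condition holds. The detector can only
fire at or after the true onset; at study-typical excursion slopes its
threshold-clearing latency is under ~3 min, and its false-alarm rate on
stationary noise is below 5%.

**Excursion metrics** (`excursion_metrics`): peak $\Delta G$ in
$[0, 90]$ min; peak derivative in $[0, 30]$ min; half-max recovery as the
first post-peak crossing of half the peak with linear interpolation
between samples; plateau as the first 60-s run with
$|dG/dt| \le 0.1 \times$ peak rise rate; return to baseline as the first
$\Delta G \le 0$, with a sustained derivative-relaxation fallback; and
positive-only iAUC, the trapezoidal integral of $\max(\Delta G, 0)$ over
$[0, 90]$ min (mg/dL·min).

## Photometry pipeline

`process_fp` chains:

1. **Motion correction**: ordinary least squares of the signal on the
   reference, `signal ~ a + b*reference`; the fitted affine component is
   subtracted. This removes everything the two channels share
   (bleaching drift, motion) exactly in the noise-free limit. A
   limitation inherent to the affine form: any chance correlation
   between a monotone drift and slow neural activity leaks a small
   drift-shaped component into the corrected trace; substantial shared
   motion dilutes this leak.
2. **Cleaning + low-pass**: the glucose cleaning chain, then a
   zero-phase (forward-backward) Butterworth low-pass, order 3, cutoff
   expressed as a 4-min period. Edge handling is odd-reflection padding
   of length $\min(n-1,\ 3 \times \lceil \text{period}_s \rceil)$ with
   the mean removed before filtering and restored afterwards, so DC is
   preserved exactly.
3. **Baseline z-scoring** over $[-25, 0]$ min.

Note a consequence of baseline z-scoring: when the anticipatory dip
begins *inside* the baseline window, a session with a larger response
also has a larger baseline SD, so part of the per-session amplitude is
divided out. Amplitude comparisons across sessions are therefore made
on the model's $\beta_1$ fitted to traces on a common scale, and the
package's amplitude-recovery guarantees are stated for traces provided
in z units.

**Band-power onset** (`lf_onset`): a sliding 20-min Hann-window
spectrogram with 99% overlap, averaged over the band of periods 14-20
min, is compared per time bin $\tau \in [-10, 10]$ min against the same
statistic at 200 pseudo-event times drawn uniformly (without
replacement) at least 5 min from the true event with full window
support. The upper-tail rank p-value is
$p(\tau) = (1 + \#\{P_{null} \ge P_{real}\}) / (N + 1)$, bounded in
$[1/(N+1), 1]$; the onset is the first $\tau$ with $p < 0.05$. The
spectrogram is computed for *all* window starts in one pass (each FFT
bin of a sliding windowed DFT is a FIR filter), so the null costs
nothing extra. This construction detects band-limited power that is
localized around the event; power that persists throughout the session
is, by design, absorbed into the null.

**Aperiodic exponent** (`psd_slope`): Welch PSD of the baseline segment
(8-min Hann segments, 50% overlap, per-segment demeaning), then an OLS
fit of $\log_{10}$ PSD on $\log_{10} f$ over $[1/600, 1/60]$ Hz;
$k$ is minus the slope.

## Early-response template model

`early_response()` fits, per session $i$,
$$\hat F_i(t) = \beta_{0i} + \beta_{1i}\, T(t - \tau^*),$$
over the fit window $[-25, +1]$ min, where $T$ is the across-session
*pointwise median* of the training-dose sessions (defaults: doses 1, 2,
2.5 g/kg) and $\tau^*$ is a single cohort-level lag from the grid
$\{-1, -0.75, \dots, 1\}$ min.

$\tau^*$ is chosen by K-fold cross-validation (default $K = 5$, folds
stratified by subject): for each candidate lag the template is rebuilt
from the held-in folds, $\beta$ is fit by pooled least squares, and the
validation MSE is accumulated on the held-out fold. All lags are scored
on the *common core* of the fit window — the window shrunk by the
largest $|\tau|$ at both ends — so every candidate is evaluated on
identical time points. (Scoring each lag on its own admissible points
silently favours lags that trim the steepest, highest-variance end of
the window: a selection artifact, not fit quality.) Ties go to higher
validation $R^2$, then smaller $|\tau|$.

Predictions must extend beyond the fit window, so the default
*two-template* scheme builds a full-span extension template from the
held-out low-dose sessions (water and 0.5 g/kg, which share the
anticipatory response but have little late glucose-driven activity),
affine-calibrated to the training template on the fit window. The
decomposition `trace = prediction + residual` holds exactly by
construction; the residual carries the second phase. A known bias of
the scheme: the 0.5 g/kg extension sessions contain a small second
phase of their own, so a fraction of early second-phase activity is
absorbed into the prediction, shifting the residual's apparent lag
behind the glucose derivative upward by roughly a minute.

The fitted object is a classed S3 model with `print`, `summary`,
`coef`, `fitted`, `residuals`, `predict` (including new sessions) and
`plot` methods.

```{r early-demo}
cohort <- simulate_cohort(synthetic_config(n_subjects = 3), seed = 7)
fit <- early_response(cohort)
fit
plot(fit, session = 2)
```

## Coupling

`coupling_analysis` computes, per session, the Spearman rank correlation
$\rho(\lambda)$ of a photometry-derived series $x(t)$ with a
glucose-derived series $y(t - \lambda)$ over their overlap, for
$\lambda \in [-20, 20]$ min (positive lag = photometry follows glucose).
The C++ fast path precomputes one global sort per series and extracts
per-window midranks in linear time per lag; it matches
`cor(..., method = "spearman")` to machine precision, including ties.
Sessions aggregate per lag in Fisher z-space,
$\rho_g = \tanh(\mathrm{mean}(\mathrm{atanh}\,\rho_i))$. The peak is the
most *negative* group correlation (the couplings studied are
inhibitory), ties toward the smallest $|\lambda|$, then the negative
lag.

Significance uses a **pseudosession null**: each session's $x$ is paired
with circular shifts (offset at least 20 min, either direction) of
*other* sessions' $y$; per lag, a two-sided Wilcoxon rank-sum test of
observed versus null correlations is Benjamini-Hochberg adjusted across
the full lag grid as one family. The circular-shift construction
presumes stationary series; applied to nonstationary inputs (for
example random walks) the null is mismatched and the nominal false
discovery rate is not guaranteed.

## Cohort statistics

`session_table` produces one row per session (glucose metrics,
photometry metrics, model coefficients, residual metrics).
`build_report` runs a fixed set of comparisons — dose against the
glucose metrics; peak inhibition against dose and glucose metrics (the
invariance checks); residual magnitude against the rates; the model's
$\beta_1$ against the rates with dose and baseline glucose as
covariates — each as OLS with subject fixed effects and HC3 robust
standard errors, with optional Benjamini-Hochberg adjustment *within*
each declared family. `one_sample_t` accepts printed summary statistics
(mean, SEM, n) so reported group results can be checked directly.

## Synthetic generator: scope

`simulate_cohort(cfg, seed)` generates each subject once per dose in a
randomized order; identical `(cfg, seed)` reproduces the identical
cohort, and every session carries its ground truth. Defaults (all
overridable in `synthetic_config()`):

* **Glucose**: baseline 150 mg/dL; a smooth $\sin^2$ rise then
  exponential fall beginning $3.6 \pm 0.5$ min after the event, with
  peak ($60 \cdot$ dose mg/dL), maximal rise rate ($5 \cdot$ dose
  mg/dL/min) and fall rate ($2 \cdot$ dose mg/dL/min) all proportional
  to dose — so the rise duration and recovery time constant are
  dose-invariant while amplitude scales; sensor noise SD 2 mg/dL;
  impulsive artifacts at 4/h.
* **Photometry**: an anticipatory inhibition template starting 4 min
  *before* the event (depth 2.5 baseline-SD units, dose-invariant,
  per-session scale $1 + \mathcal N(0, 0.25)$ as the trial "state"
  variable); a second phase equal to $-0.15 \times$ the positive part
  of the glucose derivative delayed by 5 min; $1/f$ noise (SD 1);
  bleaching drift (5%/h) and smoothed shared motion carried affinely by
  the isosbestic reference.

The generator reproduces the *statistical structure the pipeline
assumes* and nothing more. It does not emulate: meal-anticipatory
circadian effects, sensory-cue responses before the gavage contact,
multi-compartment glucose kinetics or insulin dynamics, hardware
artifacts other than spikes/drift/motion, inter-subject differences in
kinetics, or any learning across sessions.

## Problem sizes and verification

All stochastic guarantees in the test suite are checked at sizes chosen
by this package (its own choice, balancing power against a
single-CPU test budget): 100 noise seeds for onset false alarms, 60
replicates for band-power null calibration and detection, 20 synthetic
cohorts for model recovery, 10 generator seeds for coupling
directionality, and 50 replicates for FDR calibration. Core numerics
(cleaning chain, derivative, areas, lagged Spearman, fixed-effects OLS,
exact Wilcoxon) are verified against independent brute-force oracles to
at most $10^{-10}$ relative error.

The coupling-directionality check runs at half the default photometry
noise: the quantity under test is the generator's 5-min second-phase
lag, and at full noise the location of a broad rank-correlation minimum
jitters by several minutes across seeds even though the machinery is
exact (truth-against-truth coupling peaks at 5.00 min in every seed).

## Limitations

* The affine motion correction cannot separate drift that happens to
  correlate with slow neural activity (see above); experiments with
  large monotone bleaching and little motion will show a small leak.
* The global-MAD despiker can shave extreme genuine excursions at very
  low noise.
* Baseline z-scoring absorbs part of the per-session response scale
  when the response begins inside the baseline window.
* The two-template prediction absorbs a small part of the early second
  phase (upward lag bias of about one minute).
* The pseudosession null requires stationarity; the band-power onset
  null requires the oscillation of interest to be time-localized.
* Onset detection reports threshold-crossing times, which lag true
  physiological onsets by a slope-dependent latency.
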