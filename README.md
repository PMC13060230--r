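# glycofp

Joint analysis of fiber-photometry calcium recordings and continuous
(1 Hz) arterial glucose around an oral glucose challenge.

Hypothalamic AgRP neurons are rapidly inhibited when an animal ingests
nutrients — before any glucose reaches the blood. When photometry and
arterial glucose are recorded together around an oral gavage, the neural
response separates into two parts: a stereotyped, dose-invariant **early
inhibition** that begins minutes *before* the blood-glucose rise, and a
slower **second phase** that tracks the *rate of change* of blood glucose
with a lag of a few minutes. `glycofp` implements the full analysis chain
for such paired sessions:

* **Session handling** — a validated 1 Hz session container
  (`fp_session`), CSV round-trip (`save_session` / `load_session`),
  stream alignment onto a common event-anchored grid (`align_streams`),
  and cohort manifests.
* **Glucose pipeline** — robust despiking + median filter + causal moving
  average (`clean_trace`), baseline subtraction, smoothed derivative,
  sustained-rise onset detection (`detect_onset`), excursion metrics
  (peak ΔG, peak rate, half-max recovery, plateau, return, positive-only
  iAUC).
* **Photometry pipeline** — isosbestic motion correction
  (`motion_correct`), zero-phase Butterworth low-pass, baseline
  z-scoring (`process_fp`), response metrics, band-power onset detection
  against a jittered pseudo-event null (`lf_onset`), and aperiodic 1/f^k
  spectral slope (`psd_slope`).
* **Early-response template model** — the package's central fitting
  function `early_response()` returns a classed S3 object with `print`,
  `summary`, `coef`, `fitted`, `residuals`, `predict` and `plot`
  methods. A robust across-session template is regressed onto each
  session with per-session affine coefficients and one cohort-level lag
  chosen by cross-validation; the residual isolates the second phase.
* **Coupling** — lagged Spearman cross-correlation (C++ fast path),
  Fisher-z aggregation, pseudosession circular-shift nulls, per-lag
  Benjamini–Hochberg significance (`coupling_analysis`).
* **Cohort statistics** — session metric tables, fixed-effects OLS with
  HC3 robust errors, Wilcoxon tests, and a structured comparison report
  (`build_report`).
* **Synthetic cohorts** — a seeded generator (`simulate_cohort`) that
  reproduces the assumed statistical structure (dose-scaled excursions,
  dose-invariant anticipatory inhibition, rate-coupled second phase,
  1/f noise, bleaching, shared motion) with full ground truth attached,
  used throughout the tests.

## Worked example

A group-level early inhibition reported as mean −4.0 z (SEM 0.99,
n = 22 sessions) is strongly significant:

```r
library(glycofp)
r <- one_sample_t(-4.0, sem = 0.99, n = 22)
sprintf("t(%d) = %.2f, p = %.4f", r$df, r$t, r$p)
#> "t(21) = -4.04, p = 0.0006"
```

## A full cohort analysis

```r
library(glycofp)

cohort <- simulate_cohort(synthetic_config(), seed = 42)
fit <- early_response(cohort)
fit
#> Early-response template model
#>   lag tau* = +0.00 min (CV over {-1.00, -0.75, -0.50, -0.25,  0.00,  0.25,  0.50,  0.75,  1.00} min)
#>   18 training, 12 held-out low-dose, 0 other sessions
#>   CV MSE at tau*: 0.4791

tab <- session_table(cohort, fit = fit)
head(tab[, c("subject","dose","theta","peak_dg","iauc","peak_inhibition","beta1")])
#>  subject dose theta peak_dg    iauc peak_inhibition beta1
#>      m01  0.0    NA    0.97    9.89           -3.03  0.64
#>      m01  2.5  5.87  130.31 5321.73           -2.78  0.98
#>      m01  2.0  5.35  102.20 4237.57           -4.03  1.09
#>      m01  1.0  5.10   50.30 2114.12           -5.00  0.99
#>      m01  0.5  4.97   24.82 1030.53           -4.67  1.15
#>      m02  2.0  4.53  102.41 4244.99           -3.20  0.73

report <- build_report(tab, adjust_within_family = TRUE)
report[report$family == "dose_vs_bg", c("comparison","estimate","r2","p_adj")]
#>              comparison estimate    r2    p_adj
#>          peak dG ~ dose    51.73 1.000 9.82e-38
#>  BG rate of rise ~ dose     4.61 0.780 2.08e-08
#>  BG rate of fall ~ dose     0.29 0.145 5.86e-01
#>             iAUC ~ dose  2122.94 1.000 2.62e-42
```

The glucose excursion scales strongly with dose, while the peak early
inhibition does not (`peak inhibition ~ dose`: slope 0.19, adjusted
p = 0.67) — the generator's built-in dose invariance, recovered by the
pipeline.

Second-phase coupling on the same cohort:

```r
xs <- lapply(which(fit$coef$dose >= 1), function(i) fit$residual[, i])
ys <- lapply(which(fit$coef$dose >= 1),
             function(i) glucose_metrics(cohort[[i]])$dgdt)
coupling_analysis(xs, ys, coupling_config(lag_step = 5))$peak$lag / 60
# peak (most negative) correlation at a positive lag of ~5 min:
# the residual inhibition follows the glucose rate of rise
```

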