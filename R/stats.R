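#' One-sample Student's t-test from summary statistics or raw samples
#'
#' Accepts either printed summary statistics (mean, SEM, n) — as when
#' checking a reported group result — or a raw sample vector.
#'
#' @param mean sample mean, or the raw samples if \code{sem} is missing.
#' @param sem standard error of the mean.
#' @param n sample size.
#' @param mu null value.
#' @return List: \code{t}, \code{df}, \code{p} (two-sided).
#' @export
one_sample_t <- function(mean, sem = NULL, n = NULL, mu = 0) {
  if (is.null(sem)) {
    x <- mean
    n <- length(x)
    stopifnot(n >= 2)
    mean <- base::mean(x)
    sem <- stats::sd(x) / sqrt(n)
  }
  stopifnot(n >= 2)
  if (sem <= 0) stop("sem must be positive")
  tval <- (mean - mu) / sem
  df <- n - 1
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df))
}

#' Wilcoxon signed-rank test (paired)
#'
#' Two-sided; exact for small samples without ties (via
#' \code{stats::wilcox.test}). All-zero differences return p = 1 with a
#' warning.
#'
#' @param a,b paired samples.
#' @return List: \code{statistic} (V), \code{p}.
#' @export
wilcoxon_paired <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- a - b
  if (all(d == 0)) {
    warning("all paired differences are zero; p = 1")
    return(list(statistic = NA_real_, p = 1))
  }
  if (sum(d != 0) < 3) stop("need at least 3 non-zero differences")
  w <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE))
  list(statistic = unname(w$statistic), p = w$p.value)
}

#' Wilcoxon rank-sum (Mann-Whitney U) test
#'
#' @param a,b independent samples.
#' @return List: \code{statistic} (W), \code{p} (two-sided).
#' @export
wilcoxon_unpaired <- function(a, b) {
  w <- suppressWarnings(stats::wilcox.test(a, b))
  list(statistic = unname(w$statistic), p = w$p.value)
}

#' OLS with subject fixed effects and robust (HC3) standard errors
#'
#' Within-subject estimator via subject indicator variables, optionally
#' adjusting for covariates (e.g. dose, baseline glucose);
#' heteroskedasticity-consistent HC3 standard errors and a two-sided
#' confidence interval for the slope of \code{x}.
#'
#' @param y response.
#' @param x continuous predictor of interest.
#' @param subject subject labels (fixed effects).
#' @param covariates optional data frame of additional covariates.
#' @param conf_level confidence level.
#' @return List: \code{slope}, \code{se} (HC3), \code{ci}, \code{p},
#'   \code{r2}, and the underlying \code{lm} fit.
#' @export
ols_fixed_effects <- function(y, x, subject, covariates = NULL,
                              conf_level = 0.95) {
  subject <- factor(subject)
  if (nlevels(subject) < 2) stop("need at least 2 subjects")
  df <- data.frame(y = y, x = x, subject = subject)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  rhs <- c("x", names(covariates), "subject")
  form <- stats::as.formula(paste("y ~", paste(rhs, collapse = " + ")))
  fit <- stats::lm(form, data = df)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop(sprintf("design rank-deficient; collinear term(s): %s",
                 paste(bad, collapse = ", ")))
  }
  vc <- sandwich::vcovHC(fit, type = "HC3")
  ct <- lmtest::coeftest(fit, vcov. = vc)
  slope <- ct["x", "Estimate"]
  se <- ct["x", "Std. Error"]
  dfree <- fit$df.residual
  tq <- stats::qt(1 - (1 - conf_level) / 2, dfree)
  list(slope = slope, se = se, ci = c(slope - tq * se, slope + tq * se),
       p = ct["x", "Pr(>|t|)"], r2 = summary(fit)$r.squared, fit = fit)
}

#' Build a session-level metric table for a cohort
#'
#' One row per session: subject, dose, baseline glucose, glucose excursion
#' metrics, photometry response metrics, early-model coefficients and
#' residual metrics. This is the input to \code{\link{build_report}}.
#'
#' @param sessions list of \code{\link{fp_session}}.
#' @param fit optional fitted \code{\link{early_response}} for the same
#'   sessions (same order); when supplied, beta0/beta1/r2 and residual
#'   metrics are included.
#' @param clean_cfg,onset_cfg,fp_cfg configuration objects.
#' @return A data frame (class \code{"session_table"}).
#' @export
session_table <- function(sessions, fit = NULL,
                          clean_cfg = clean_config(),
                          onset_cfg = onset_config(),
                          fp_cfg = fp_config()) {
  rows <- lapply(seq_along(sessions), function(i) {
    s <- sessions[[i]]
    gm <- glucose_metrics(s, clean_cfg, onset_cfg)
    Z <- if (!is.null(fit)) fit$z[, i] else process_fp(s, fp_cfg)
    pm <- response_metrics(Z, s$t, gm$peak_dg_time, fp_cfg)
    base_bg <- mean(clean_trace(s$glucose,
                                clean_cfg)[s$t >= -25 * 60 & s$t <= 0])
    row <- data.frame(
      subject = s$subject_id, dose = s$dose,
      session_order = s$session_order, baseline_bg = base_bg,
      theta = gm$theta, peak_dg = gm$peak_dg,
      peak_dg_time = gm$peak_dg_time, peak_deriv = gm$peak_deriv,
      peak_deriv_time = gm$peak_deriv_time,
      half_max_time = gm$half_max_time, return_time = gm$return_time,
      iauc = gm$iauc, peak_z = pm$peak_z,
      peak_inhibition = pm$peak_inhibition,
      peak_inhibition_time = pm$peak_inhibition_time,
      neg_auc = pm$neg_auc, total_auc = pm$total_auc,
      stringsAsFactors = FALSE)
    if (!is.null(fit)) {
      rm_ <- residual_metrics(fit$residual[, i], s$t)
      row$beta0 <- fit$coef$beta0[i]
      row$beta1 <- fit$coef$beta1[i]
      row$r2 <- fit$coef$r2[i]
      row$resid_min <- rm_$peak_inhibition
      row$resid_min_time <- rm_$peak_inhibition_time
      row$resid_neg_auc <- rm_$neg_auc
    }
    row
  })
  out <- do.call(rbind, rows)
  class(out) <- c("session_table", class(out))
  out
}

fe_row <- function(tab, y, x, label, covariates = NULL) {
  ok <- stats::complete.cases(tab[[y]], tab[[x]])
  if (!is.null(covariates))
    ok <- ok & stats::complete.cases(tab[covariates])
  d <- tab[ok, , drop = FALSE]
  cov_df <- if (is.null(covariates)) NULL else d[covariates]
  r <- tryCatch(
    ols_fixed_effects(d[[y]], d[[x]], d$subject, cov_df),
    error = function(e) NULL)
  if (is.null(r))
    return(data.frame(comparison = label, estimate = NA_real_,
                      se = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                      r2 = NA_real_, p = NA_real_, n = sum(ok),
                      test = "OLS-FE (HC3)", stringsAsFactors = FALSE))
  data.frame(comparison = label, estimate = r$slope, se = r$se,
             ci_lo = r$ci[1], ci_hi = r$ci[2], r2 = r$r2, p = r$p,
             n = sum(ok), test = "OLS-FE (HC3)", stringsAsFactors = FALSE)
}

#' Cohort comparison report
#'
#' Reproduces the cohort-level comparison structure: dose against glucose
#' excursion metrics (peak \eqn{\Delta G}, rates of rise and fall, iAUC);
#' peak photometry inhibition against dose and glucose metrics (the
#' invariance checks); residual (second-phase) magnitude against the rates
#' of rise and fall; and the early-model slope \eqn{\beta_1} against the
#' rates with dose and baseline glucose as covariates. All slopes come from
#' OLS with subject fixed effects and HC3 robust errors. Benjamini-Hochberg
#' adjustment is applied within each declared family; the default families
#' leave session-level comparisons unadjusted (each its own family).
#'
#' @param tab a \code{\link{session_table}}.
#' @param adjust_within_family apply BH within each report section.
#' @return Data frame of comparisons: estimate, robust SE, CI, R^2, test,
#'   p (and \code{p_adj} when adjusted).
#' @export
build_report <- function(tab, adjust_within_family = FALSE) {
  tab$rate_rise <- tab$peak_deriv
  tab$rate_fall <- NA_real_
  # rate of fall: peak to half-max drop per minute (positive number)
  ok <- !is.na(tab$half_max_time) & !is.na(tab$peak_dg)
  tab$rate_fall[ok] <- (0.5 * tab$peak_dg[ok]) /
    pmax(tab$half_max_time[ok] - tab$peak_dg_time[ok], 1e-6)
  fam <- list(
    dose_vs_bg = rbind(
      fe_row(tab, "peak_dg", "dose", "peak dG ~ dose"),
      fe_row(tab, "rate_rise", "dose", "BG rate of rise ~ dose"),
      fe_row(tab, "rate_fall", "dose", "BG rate of fall ~ dose"),
      fe_row(tab, "iauc", "dose", "iAUC ~ dose")),
    inhibition_invariance = rbind(
      fe_row(tab, "peak_inhibition", "dose", "peak inhibition ~ dose"),
      fe_row(tab, "peak_inhibition", "peak_dg",
             "peak inhibition ~ peak dG"),
      fe_row(tab, "peak_inhibition", "rate_rise",
             "peak inhibition ~ rate of rise"),
      fe_row(tab, "peak_inhibition", "rate_fall",
             "peak inhibition ~ rate of fall")),
    residual_vs_rates = if ("resid_min" %in% names(tab)) rbind(
      fe_row(tab, "resid_min", "peak_dg", "residual min ~ peak dG"),
      fe_row(tab, "resid_min", "rate_rise", "residual min ~ rate of rise"),
      fe_row(tab, "resid_min", "rate_fall", "residual min ~ rate of fall"))
      else NULL,
    state_slope = if ("beta1" %in% names(tab)) rbind(
      fe_row(tab, "rate_rise", "beta1",
             "rate of rise ~ beta1 | dose + baseline BG",
             covariates = c("dose", "baseline_bg")),
      fe_row(tab, "rate_fall", "beta1",
             "rate of fall ~ beta1 | dose + baseline BG",
             covariates = c("dose", "baseline_bg"))) else NULL)
  out <- do.call(rbind, c(lapply(names(fam), function(nm) {
    f <- fam[[nm]]
    if (is.null(f)) return(NULL)
    f$family <- nm
    if (adjust_within_family) f$p_adj <- stats::p.adjust(f$p, "BH")
    f
  }), list(make.row.names = FALSE)))
  out
}
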