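#' Early-response model configuration
#'
#' @param fit_window window used for all template fitting, minutes relative
#'   to the event (pre/early activity only).
#' @param lag_grid candidate temporal offsets \eqn{\tau}, minutes.
#' @param k_folds cross-validation folds across training sessions.
#' @param train_doses g/kg doses defining the training set.
#' @param test_doses g/kg doses held out entirely (water/low dose); their
#'   across-session median supplies the full-span template extension.
#' @param template_scheme \code{"two"} (default): fit against the
#'   training-dose template on the fit window, predict with the held-out
#'   low-dose template extension affine-calibrated to it; \code{"single"}:
#'   fit and predict with the low-dose extension template only.
#' @return List of class \code{"early_config"}.
#' @export
early_config <- function(fit_window = c(-25, 1),
                         lag_grid = seq(-1, 1, by = 0.25),
                         k_folds = 5,
                         train_doses = c(1, 2, 2.5),
                         test_doses = c(0, 0.5),
                         template_scheme = c("two", "single")) {
  stopifnot(length(intersect(train_doses, test_doses)) == 0,
            k_folds >= 2)
  if (max(abs(sort(lag_grid) + rev(sort(lag_grid)))) > 1e-9)
    stop("lag_grid must be symmetric about 0")
  structure(list(fit_window = fit_window, lag_grid = lag_grid,
                 k_folds = k_folds, train_doses = train_doses,
                 test_doses = test_doses,
                 template_scheme = match.arg(template_scheme)),
            class = "early_config")
}

# Value of a template shifted by tau minutes, evaluated on t (seconds):
# shifted(t) = template(t - tau). rule = 2 extends by the edge value, used
# only for the full-span extension where the shift leaves a <= |tau| gap.
shift_template <- function(template, t_eval, tau_min, rule = 1) {
  stats::approx(template$t + tau_min * 60, template$value, xout = t_eval,
                rule = rule)$y
}

#' Build a pointwise-median template
#'
#' Across-session median at each time point, robust to outlying sessions.
#'
#' @param z_list list of z-scored traces on a shared grid.
#' @param t shared time axis, seconds.
#' @param window restriction window in minutes, or \code{NULL} for the full
#'   span.
#' @return List with \code{t} (seconds) and \code{value}.
#' @export
build_template <- function(z_list, t, window = NULL) {
  if (length(z_list) == 0) stop("no sessions supplied for the template")
  idx <- if (is.null(window)) seq_along(t) else
    which_window(t, window[1] * 60, window[2] * 60)
  m <- vapply(z_list, function(z) z[idx], numeric(length(idx)))
  list(t = t[idx], value = apply(m, 1, stats::median))
}

#' Lagged affine template regression for one session
#'
#' Ordinary least squares of the session trace on the time-shifted template,
#' \eqn{\hat F(t; \tau) = \beta_0 + \beta_1 F_{templ}(t - \tau)}, over the
#' fit window (restricted to where the shifted template is defined; at
#' least 90\% of the window must overlap).
#'
#' @param z session z-scored trace.
#' @param t time axis, seconds.
#' @param template list with \code{t}, \code{value} (see
#'   \code{\link{build_template}}).
#' @param tau candidate lag, minutes.
#' @param window fit window, minutes.
#' @return List: \code{beta0}, \code{beta1}, \code{mse}, \code{r2}.
#' @export
fit_template_regression <- function(z, t, template, tau,
                                    window = c(-25, 1)) {
  idx <- which_window(t, window[1] * 60, window[2] * 60)
  x <- shift_template(template, t[idx], tau)
  ok <- !is.na(x)
  if (sum(ok) < 0.9 * length(idx))
    stop("shifted template overlaps less than 90% of the fit window")
  x <- x[ok]; y <- z[idx][ok]
  if (stats::sd(x) == 0)
    stop("template constant over the fit window: slope unidentifiable")
  fit <- stats::lm.fit(cbind(1, x), y)
  res <- fit$residuals
  mse <- mean(res^2)
  sst <- sum((y - mean(y))^2)
  list(beta0 = unname(fit$coefficients[1]),
       beta1 = unname(fit$coefficients[2]),
       mse = mse, r2 = if (sst > 0) 1 - sum(res^2) / sst else NA_real_)
}

# Assign sessions to folds, stratified by subject (each subject's sessions
# spread across folds) when counts allow.
make_folds <- function(subject, k) {
  n <- length(subject)
  fold <- integer(n)
  pos <- 0L
  for (s in unique(subject)) {
    idx <- which(subject == s)
    fold[idx] <- ((pos + seq_along(idx) - 1L) %% k) + 1L
    pos <- pos + length(idx)
  }
  fold
}

#' Cross-validated lag selection
#'
#' K-fold cross-validation across training sessions (folds stratified by
#' subject when subject counts allow). For each candidate lag the template
#' is rebuilt from the K-1 held-in folds, \eqn{\beta_0, \beta_1} are fit by
#' pooled least squares across those sessions over the fit window, and the
#' validation MSE is accumulated on the left-out fold. All candidate lags
#' are scored on the common core of the fit window (the window shrunk by
#' the largest candidate \eqn{|\tau|} at both ends), so every lag is
#' evaluated on identical time points and MSEs are directly comparable.
#' The selected \eqn{\tau^*} minimises mean validation MSE (ties broken by
#' higher validation \eqn{R^2}, then by smaller \eqn{|\tau|}).
#'
#' @param z_list list of training-session traces.
#' @param t shared time axis, seconds.
#' @param subject subject label per session.
#' @param cfg an \code{\link{early_config}}.
#' @return List: \code{tau_star} and \code{cv} (data frame of \code{tau},
#'   \code{mse}, \code{r2}).
#' @export
select_lag_cv <- function(z_list, t, subject, cfg = early_config()) {
  n <- length(z_list)
  k <- cfg$k_folds
  if (n < k) {
    warning(sprintf("only %d training sessions: reducing folds from %d to %d",
                    n, k, n))
    k <- n
  }
  fold <- make_folds(subject, k)
  # common scoring support: shrink the fit window by the largest |tau| so
  # every candidate lag is evaluated on identical time points
  m <- max(abs(cfg$lag_grid))
  idx_w <- which_window(t, (cfg$fit_window[1] + m) * 60,
                        (cfg$fit_window[2] - m) * 60)
  cv <- data.frame(tau = cfg$lag_grid, mse = NA_real_, r2 = NA_real_)
  for (j in seq_along(cfg$lag_grid)) {
    tau <- cfg$lag_grid[j]
    sse <- 0; sst <- 0; npts <- 0
    for (kk in seq_len(k)) {
      hold <- which(fold == kk)
      keep <- which(fold != kk)
      templ <- build_template(z_list[keep], t, cfg$fit_window)
      x <- shift_template(templ, t[idx_w], tau)
      ok <- !is.na(x)
      # pooled fit across held-in sessions
      xs <- rep(x[ok], length(keep))
      ys <- unlist(lapply(z_list[keep], function(z) z[idx_w][ok]))
      fit <- stats::lm.fit(cbind(1, xs), ys)
      b <- fit$coefficients
      for (i in hold) {
        yv <- z_list[[i]][idx_w][ok]
        pv <- b[1] + b[2] * x[ok]
        sse <- sse + sum((yv - pv)^2)
        sst <- sst + sum((yv - mean(yv))^2)
        npts <- npts + length(yv)
      }
    }
    cv$mse[j] <- sse / npts
    cv$r2[j] <- if (sst > 0) 1 - sse / sst else NA_real_
  }
  ord <- order(cv$mse, -cv$r2, abs(cv$tau))
  list(tau_star = cv$tau[ord[1]], cv = cv)
}

#' Fit the early-response template model to a cohort
#'
#' The model isolates the stereotyped, dose-agnostic early inhibition from
#' later feedback-like activity. A robust template (across-session pointwise
#' median of training-dose sessions over the fit window) is regressed onto
#' each session with a per-session intercept \eqn{\beta_0} and scale
#' \eqn{\beta_1} and a single cohort-level lag \eqn{\tau^*} chosen by inner
#' K-fold cross-validation. Full-session predictions use the held-out
#' low-dose (water/0.5 g/kg) median trace, affine-calibrated to the training
#' template on the fit window, so predictions extend beyond the fit window;
#' residuals \eqn{R_i(t) = F_i(t) - \hat F_i(t; \tau^*)} carry the
#' second-phase activity.
#'
#' @param sessions list of \code{\link{fp_session}} objects, or a list of
#'   pre-computed z-scored traces (then \code{t}, \code{dose},
#'   \code{subject} must be given).
#' @param config an \code{\link{early_config}}.
#' @param fp_cfg an \code{\link{fp_config}} used to process raw sessions.
#' @param t,dose,subject required when \code{sessions} is a plain list of
#'   traces.
#' @return Object of class \code{"early_response"}: \code{tau_star},
#'   \code{cv}, \code{template_fit}, \code{template_ext} (calibrated),
#'   \code{coef} (per-session \code{beta0}, \code{beta1}, \code{r2},
#'   \code{role}), matrices \code{z}, \code{prediction}, \code{residual}
#'   (sessions in columns), and the inputs' metadata.
#' @export
early_response <- function(sessions, config = early_config(),
                           fp_cfg = fp_config(), t = NULL, dose = NULL,
                           subject = NULL) {
  if (length(sessions) > 0 && inherits(sessions[[1]], "fp_session")) {
    t <- sessions[[1]]$t
    dose <- vapply(sessions, `[[`, 0, "dose")
    subject <- vapply(sessions, `[[`, "", "subject_id")
    z_list <- lapply(sessions, process_fp, cfg = fp_cfg)
  } else {
    stopifnot(!is.null(t), !is.null(dose), !is.null(subject))
    z_list <- sessions
  }
  is_train <- dose %in% config$train_doses
  is_test <- dose %in% config$test_doses
  if (sum(is_train) < 2) stop("need at least 2 training-dose sessions")
  if (config$template_scheme == "two" && sum(is_test) == 0)
    stop("two-template scheme needs held-out low-dose sessions; none found")

  sel <- select_lag_cv(z_list[is_train], t, subject[is_train], config)
  tau_star <- sel$tau_star
  template_fit <- build_template(z_list[is_train], t, config$fit_window)

  # full-span extension from held-out low-dose sessions, affine-calibrated
  # to the training template on the fit window
  if (config$template_scheme == "two") {
    ext_raw <- build_template(z_list[is_test], t, window = NULL)
    idx_w <- which_window(t, config$fit_window[1] * 60,
                          config$fit_window[2] * 60)
    xe <- ext_raw$value[match(t[idx_w], ext_raw$t)]
    fitc <- stats::lm.fit(cbind(1, xe), template_fit$value)
    template_ext <- list(t = ext_raw$t,
                         value = fitc$coefficients[1] +
                           fitc$coefficients[2] * ext_raw$value)
    fit_templ <- template_fit
  } else {
    template_ext <- build_template(z_list[is_test], t, window = NULL)
    fit_templ <- template_ext
  }

  S <- length(z_list)
  cf <- data.frame(subject = subject, dose = dose,
                   role = ifelse(is_train, "train",
                                 ifelse(is_test, "test", "other")),
                   beta0 = NA_real_, beta1 = NA_real_, r2 = NA_real_,
                   stringsAsFactors = FALSE)
  zmat <- matrix(unlist(z_list), ncol = S)
  pred <- matrix(NA_real_, nrow = length(t), ncol = S)
  for (i in seq_len(S)) {
    fi <- fit_template_regression(z_list[[i]], t, fit_templ, tau_star,
                                  config$fit_window)
    cf$beta0[i] <- fi$beta0; cf$beta1[i] <- fi$beta1; cf$r2[i] <- fi$r2
    ext_shift <- shift_template(template_ext, t, tau_star, rule = 2)
    pred[, i] <- fi$beta0 + fi$beta1 * ext_shift
  }
  structure(list(tau_star = tau_star, cv = sel$cv,
                 template_fit = template_fit, template_ext = template_ext,
                 coef = cf, t = t, z = zmat, prediction = pred,
                 residual = zmat - pred, config = config),
            class = "early_response")
}

#' Predict and decompose a single session against a fitted model
#'
#' Estimates \eqn{\beta_0, \beta_1} for the new trace on the fit window at
#' the fitted \eqn{\tau^*}, then returns the full-session prediction and
#' residual.
#'
#' @param object a fitted \code{early_response}.
#' @param z z-scored trace on the model's grid.
#' @return List: \code{beta0}, \code{beta1}, \code{r2}, \code{prediction},
#'   \code{residual}.
#' @export
predict_and_residual <- function(object, z) {
  cfg <- object$config
  fit_templ <- if (cfg$template_scheme == "two") object$template_fit else
    object$template_ext
  fi <- fit_template_regression(z, object$t, fit_templ, object$tau_star,
                                cfg$fit_window)
  p <- fi$beta0 + fi$beta1 *
    shift_template(object$template_ext, object$t, object$tau_star, rule = 2)
  list(beta0 = fi$beta0, beta1 = fi$beta1, r2 = fi$r2,
       prediction = p, residual = z - p)
}

#' Residual (second-phase) response metrics
#'
#' Minimum of the residual trace and its time over the post-event window,
#' plus the negative-clipped trapezoidal integral.
#'
#' @param residual residual series.
#' @param t time axis, seconds.
#' @param window post-event window, minutes.
#' @return List: \code{peak_inhibition}, \code{peak_inhibition_time} (min),
#'   \code{neg_auc} (z*min).
#' @export
residual_metrics <- function(residual, t, window = c(0, 60)) {
  idx <- which_window(t, window[1] * 60, window[2] * 60)
  imin <- idx[which.min(residual[idx])]
  list(peak_inhibition = residual[imin],
       peak_inhibition_time = t[imin] / 60,
       neg_auc = trapz(t[idx] / 60, pmin(residual[idx], 0)))
}

#' @export
print.early_response <- function(x, ...) {
  cat("Early-response template model\n")
  cat(sprintf("  lag tau* = %+.2f min (CV over {%s} min)\n", x$tau_star,
              paste(format(x$config$lag_grid), collapse = ", ")))
  cat(sprintf("  %d training, %d held-out low-dose, %d other sessions\n",
              sum(x$coef$role == "train"), sum(x$coef$role == "test"),
              sum(x$coef$role == "other")))
  cat(sprintf("  CV MSE at tau*: %.4g\n",
              x$cv$mse[which.min(abs(x$cv$tau - x$tau_star))]))
  invisible(x)
}

#' @export
summary.early_response <- function(object, ...) {
  out <- list(tau_star = object$tau_star, cv = object$cv,
              coef = object$coef)
  class(out) <- "summary.early_response"
  out
}

#' @export
print.summary.early_response <- function(x, ...) {
  cat(sprintf("Early-response model: tau* = %+.2f min\n\n", x$tau_star))
  cat("Cross-validation:\n")
  print(x$cv, row.names = FALSE)
  cat("\nPer-session coefficients:\n")
  print(x$coef, row.names = FALSE)
  invisible(x)
}

#' @export
coef.early_response <- function(object, ...) {
  object$coef[, c("beta0", "beta1")]
}

#' @export
fitted.early_response <- function(object, ...) object$prediction

#' @export
residuals.early_response <- function(object, ...) object$residual

#' @export
predict.early_response <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$prediction)
  predict_and_residual(object, newdata)$prediction
}

#' @export
plot.early_response <- function(x, session = 1, ...) {
  tm <- x$t / 60
  graphics::plot(tm, x$z[, session], type = "l", col = "grey50",
                 xlab = "time from gavage (min)", ylab = "z-score",
                 main = sprintf("session %d: trace, prediction, residual",
                                session), ...)
  graphics::lines(tm, x$prediction[, session], col = "firebrick", lwd = 2)
  graphics::lines(tm, x$residual[, session], col = "steelblue")
  graphics::abline(v = 0, lty = 2)
  graphics::legend("bottomright", legend = c("trace", "prediction",
                                             "residual"),
                   col = c("grey50", "firebrick", "steelblue"), lwd = 2,
                   bty = "n")
  invisible(x)
}
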