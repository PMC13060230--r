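# Property tests on the early-response template model, on traces built
# directly in z units so the model mechanics are isolated from the
# photometry processing chain.

t_early <- seq(-25 * 60, 90 * 60, by = 1)

make_fit_inputs <- function(z_list, n_train, n_test) {
  list(dose = c(rep(2, n_train), rep(0, n_test)),
       subject = paste0("m", rep(1:2, length.out = n_train + n_test)))
}

test_that("template regression recovers known affine coefficients exactly", {
  cfg <- early_config()
  base <- make_z_traces(1, t_early)[[1]]
  templ <- list(t = t_early, value = base)
  z <- 0.7 + 1.9 * base
  fi <- fit_template_regression(z, t_early, templ, tau = 0,
                                window = cfg$fit_window)
  expect_equal(fi$beta0, 0.7, tolerance = 1e-9)
  expect_equal(fi$beta1, 1.9, tolerance = 1e-9)
  expect_equal(fi$r2, 1, tolerance = 1e-9)
  expect_equal(fi$mse, 0, tolerance = 1e-12)
  expect_error(
    fit_template_regression(z, t_early, list(t = t_early,
                                             value = rep(1, length(t_early))),
                            0, cfg$fit_window),
    "constant")
})

test_that("pointwise-median template ignores one wild outlying session", {
  set.seed(1)
  clean <- make_z_traces(4, t_early, noise_sd = 0.01)
  wild <- list(clean[[1]] + 50 * sin(t_early / 100))
  templ_clean <- build_template(clean, t_early, c(-25, 1))
  templ_mixed <- build_template(c(clean, wild), t_early, c(-25, 1))
  expect_equal(templ_mixed$value, templ_clean$value, tolerance = 0.05)
})

test_that("cross-validation selects zero lag for identically-timed sessions", {
  set.seed(2)
  n <- 10
  z <- make_z_traces(n, t_early, scales = runif(n, 0.8, 1.2),
                     noise_sd = 0.05)
  sel <- select_lag_cv(z, t_early, subject = paste0("m", rep(1:5, each = 2)))
  expect_equal(sel$tau_star, 0)
  expect_equal(nrow(sel$cv), length(early_config()$lag_grid))
  expect_true(all(is.finite(sel$cv$mse)))
})

test_that("fitted model: decomposition identity holds exactly", {
  set.seed(3)
  n_train <- 6; n_test <- 4
  z <- make_z_traces(n_train + n_test, t_early, noise_sd = 0.1)
  meta <- make_fit_inputs(z, n_train, n_test)
  fit <- early_response(z, t = t_early, dose = meta$dose,
                        subject = meta$subject)
  expect_s3_class(fit, "early_response")
  expect_equal(fit$z, fit$prediction + fit$residual, tolerance = 1e-12)
  expect_equal(residuals(fit), fit$z - fitted(fit), tolerance = 1e-12)
  expect_false(anyNA(fit$prediction))
})

test_that("beta1 tracks the per-session scale on low-noise traces", {
  set.seed(4)
  n_train <- 12; n_test <- 4
  scales <- c(runif(n_train, 0.5, 1.5), rep(1, n_test))
  z <- make_z_traces(n_train + n_test, t_early, scales = scales,
                     noise_sd = 0.2)
  meta <- make_fit_inputs(z, n_train, n_test)
  fit <- early_response(z, t = t_early, dose = meta$dose,
                        subject = meta$subject)
  b1 <- fit$coef$beta1[fit$coef$role == "train"]
  expect_gt(cor(b1, scales[1:n_train]), 0.9)
  # the common lag of identically-timed sessions stays within one grid
  # step of zero at this noise level
  expect_lte(abs(fit$tau_star), 0.25)
})

test_that("a common timing shift moves the selected lag accordingly", {
  set.seed(5)
  n_train <- 8; n_test <- 4
  # training traces delayed 0.5 min relative to the held-out test traces:
  # with the two-template scheme, tau is selected on training traces only,
  # so their internal consistency keeps tau* = 0; instead check the
  # single-session refit against a deliberately shifted template
  z <- make_z_traces(1, t_early, noise_sd = 0)[[1]]
  templ <- build_template(make_z_traces(1, t_early, shift_min = -0.5), t_early,
                          c(-25, 1))
  cfg <- early_config()
  fits <- lapply(cfg$lag_grid, function(tau)
    fit_template_regression(z, t_early, templ, tau, cfg$fit_window))
  best <- cfg$lag_grid[which.min(vapply(fits, `[[`, 0, "mse"))]
  expect_equal(best, 0.5)
})

test_that("residual carries an injected second-phase bump", {
  set.seed(6)
  n_train <- 8; n_test <- 4
  tm <- t_early / 60
  bump <- -1.5 * exp(-((tm - 25) / 8)^2)  # late inhibition, outside fit window
  z_clean <- make_z_traces(n_train + n_test, t_early, noise_sd = 0.15)
  z <- z_clean
  z[1:n_train] <- lapply(z[1:n_train], function(x) x + bump)
  meta <- make_fit_inputs(z, n_train, n_test)
  fit <- early_response(z, t = t_early, dose = meta$dose,
                        subject = meta$subject)
  r_mean <- rowMeans(fit$residual[, 1:n_train])
  expect_gt(cor(r_mean[tm > 5], bump[tm > 5]), 0.95)
  rm <- residual_metrics(r_mean, t_early)
  expect_equal(rm$peak_inhibition_time, 25, tolerance = 3)
  expect_lt(rm$peak_inhibition, -1)
  expect_lt(rm$neg_auc, 0)
})

test_that("S3 methods print, summarise, and predict coherently", {
  set.seed(7)
  z <- make_z_traces(8, t_early, noise_sd = 0.1)
  meta <- make_fit_inputs(z, 5, 3)
  fit <- early_response(z, t = t_early, dose = meta$dose,
                        subject = meta$subject)
  expect_output(print(fit), "tau\\*")
  expect_output(print(summary(fit)), "Per-session coefficients")
  expect_equal(dim(coef(fit)), c(8L, 2L))
  expect_equal(predict(fit), fit$prediction)
  # new-session prediction reproduces the training-session decomposition
  pr <- predict_and_residual(fit, z[[1]])
  expect_equal(pr$prediction, fit$prediction[, 1], tolerance = 1e-9)
  expect_equal(pr$residual, fit$residual[, 1], tolerance = 1e-9)
  # plot method draws without error
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_invisible(plot(fit, session = 1))
})

test_that("degenerate inputs fail loudly", {
  z <- make_z_traces(3, t_early)
  expect_error(early_response(z, t = t_early, dose = c(2, 0, 0),
                              subject = c("a", "b", "c")),
               "at least 2 training")
  expect_error(early_response(z, t = t_early, dose = c(2, 2, 1),
                              subject = c("a", "b", "c")),
               "low-dose")
  expect_error(early_config(lag_grid = c(-1, 0, 0.5)), "symmetric")
  expect_error(early_config(train_doses = 1, test_doses = 1), "")
})
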