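#' Coupling analysis configuration
#'
#' @param max_lag maximal lag, minutes (correlations over
#'   \code{c(-max_lag, max_lag)}).
#' @param lag_step lag grid step, seconds.
#' @param n_null pseudosession null pairings per session.
#' @param min_shift minimum circular-shift offset for null pairings,
#'   minutes.
#' @param fdr_q Benjamini-Hochberg false-discovery level across lags.
#' @param min_overlap_min minimal overlap after shifting, minutes.
#' @return List of class \code{"coupling_config"}.
#' @export
coupling_config <- function(max_lag = 20, lag_step = 1, n_null = 200,
                            min_shift = 20, fdr_q = 0.05,
                            min_overlap_min = 10) {
  stopifnot(max_lag > 0, lag_step >= 1)
  structure(as.list(environment()), class = "coupling_config")
}

#' Lagged Spearman cross-correlation
#'
#' For each lag \eqn{\lambda} on the grid, the Spearman rank correlation of
#' \code{x(t)} with \code{y(t - \lambda)} over the overlapping support.
#' Convention: positive lag means \code{x} follows \code{y} by
#' \eqn{\lambda}. Lags where a window is constant (rank correlation
#' undefined) or the overlap is too short are \code{NA}.
#'
#' @param x photometry-derived series (1 Hz).
#' @param y glucose-derived series (1 Hz, same grid).
#' @param cfg a \code{\link{coupling_config}}.
#' @return List: \code{lag} (seconds) and \code{rho}.
#' @export
spearman_lagged_xcorr <- function(x, y, cfg = coupling_config()) {
  lags <- seq(-cfg$max_lag * 60, cfg$max_lag * 60, by = cfg$lag_step)
  rho <- lagged_spearman_cpp(as.numeric(x), as.numeric(y),
                             as.integer(lags),
                             as.integer(cfg$min_overlap_min * 60))
  list(lag = lags, rho = rho)
}

#' Pseudosession null correlation curves
#'
#' Builds a null for one photometry trace by pairing it with circular
#' shifts of \emph{other} sessions' glucose series: each of \code{n_null}
#' pairings draws a pool trace uniformly and circularly shifts it by a
#' uniform offset of at least \code{min_shift} minutes (in either
#' direction), then computes the full \eqn{\rho(\lambda)} curve.
#'
#' @param x photometry-derived series.
#' @param glucose_pool list of glucose-derived series from other sessions.
#' @param cfg a \code{\link{coupling_config}}.
#' @return Matrix of null \eqn{\rho} values, lags in rows, draws in
#'   columns.
#' @export
pseudosession_null <- function(x, glucose_pool, cfg = coupling_config()) {
  if (length(glucose_pool) == 0) stop("empty glucose pool")
  n <- length(x)
  ms <- cfg$min_shift * 60
  if (n <= 2 * ms)
    stop(sprintf("traces too short (%d s) for a %g-min minimum circular shift",
                 n, cfg$min_shift))
  lags <- seq(-cfg$max_lag * 60, cfg$max_lag * 60, by = cfg$lag_step)
  out <- matrix(NA_real_, nrow = length(lags), ncol = cfg$n_null)
  for (k in seq_len(cfg$n_null)) {
    g <- glucose_pool[[sample.int(length(glucose_pool), 1)]]
    shift <- sample(seq.int(ms, n - ms), 1)
    gs <- c(g[(shift + 1):n], g[1:shift])
    out[, k] <- lagged_spearman_cpp(as.numeric(x), as.numeric(gs),
                                    as.integer(lags),
                                    as.integer(cfg$min_overlap_min * 60))
  }
  out
}

#' Fisher-z aggregation of per-session correlations
#'
#' Per lag: \eqn{\rho_{group} = \tanh(mean(\mathrm{atanh}(\rho_i)))}.
#' Correlations at exactly \eqn{\pm 1} are clipped to
#' \eqn{\pm(1 - 10^{-6})} with a warning.
#'
#' @param rho_list list of per-session \eqn{\rho(\lambda)} vectors on the
#'   same lag grid.
#' @return Group \eqn{\rho} vector.
#' @export
aggregate_fisher <- function(rho_list) {
  stopifnot(length(rho_list) >= 1)
  m <- vapply(rho_list, as.numeric, numeric(length(rho_list[[1]])))
  if (any(abs(m) >= 1, na.rm = TRUE)) {
    warning("correlations at +/-1 clipped to +/-(1 - 1e-6)")
    m[m >= 1] <- 1 - 1e-6
    m[m <= -1] <- -(1 - 1e-6)
  }
  tanh(rowMeans(atanh(m), na.rm = TRUE))
}

#' Per-lag significance against the pseudosession null
#'
#' At each lag, a two-sided Wilcoxon rank-sum test of the observed
#' per-session correlations against the pooled null samples, followed by
#' Benjamini-Hochberg adjustment across the full lag grid as one family.
#'
#' @param observed matrix of observed \eqn{\rho}, lags in rows, sessions in
#'   columns.
#' @param null matrix of null \eqn{\rho}, lags in rows, draws in columns.
#' @param cfg a \code{\link{coupling_config}}.
#' @return List: \code{p} (raw), \code{p_adj}, \code{flag}
#'   (\code{p_adj < fdr_q}).
#' @export
significance_per_lag <- function(observed, null, cfg = coupling_config()) {
  stopifnot(nrow(observed) == nrow(null), ncol(observed) >= 3,
            ncol(null) >= 20)
  p <- vapply(seq_len(nrow(observed)), function(i) {
    o <- observed[i, ]; nl <- null[i, ]
    o <- o[!is.na(o)]; nl <- nl[!is.na(nl)]
    if (length(o) < 3 || length(nl) < 20) return(NA_real_)
    suppressWarnings(stats::wilcox.test(o, nl, exact = FALSE)$p.value)
  }, numeric(1))
  p_adj <- stats::p.adjust(p, method = "BH")
  list(p = p, p_adj = p_adj, flag = !is.na(p_adj) & p_adj < cfg$fdr_q)
}

#' Peak (most negative) lag of a group correlation curve
#'
#' The couplings studied here are inhibitory, so the peak is the most
#' negative group \eqn{\rho}. Ties are broken toward the smallest
#' \eqn{|\lambda|}; an exact \eqn{\pm\lambda} tie returns the negative lag.
#'
#' @param lag lag grid, seconds.
#' @param rho_group group correlation per lag.
#' @return List: \code{lag} (seconds) and \code{value}.
#' @export
peak_lag <- function(lag, rho_group) {
  ok <- which(!is.na(rho_group))
  v <- min(rho_group[ok])
  cand <- ok[rho_group[ok] == v]
  cand <- cand[order(abs(lag[cand]), lag[cand])]
  list(lag = lag[cand[1]], value = v)
}

#' Cohort-level lagged coupling analysis
#'
#' Computes per-session lagged Spearman correlation between a
#' photometry-derived series and a glucose-derived series, aggregates
#' across sessions in Fisher z-space, optionally evaluates per-lag
#' significance against pseudosession nulls, and locates the peak
#' (most negative) lag.
#'
#' @param x_list list of photometry-derived series (one per session).
#' @param y_list list of glucose-derived series, same order and grid.
#' @param cfg a \code{\link{coupling_config}}.
#' @param with_null compute pseudosession nulls and per-lag adjusted
#'   p-values (each session's null pool is the other sessions' \code{y}).
#' @return List of class \code{"coupling_result"}: \code{lag} (s),
#'   \code{rho} (matrix, lags x sessions), \code{rho_group},
#'   \code{peak} (list: lag s, value), and when \code{with_null},
#'   \code{p}, \code{p_adj}, \code{flag}.
#' @export
coupling_analysis <- function(x_list, y_list, cfg = coupling_config(),
                              with_null = FALSE) {
  stopifnot(length(x_list) == length(y_list), length(x_list) >= 1)
  curves <- lapply(seq_along(x_list), function(i)
    spearman_lagged_xcorr(x_list[[i]], y_list[[i]], cfg))
  lag <- curves[[1]]$lag
  rho <- vapply(curves, `[[`, numeric(length(lag)), "rho")
  rho_group <- aggregate_fisher(lapply(curves, `[[`, "rho"))
  out <- list(lag = lag, rho = rho, rho_group = rho_group,
              peak = peak_lag(lag, rho_group))
  if (with_null) {
    nulls <- lapply(seq_along(x_list), function(i)
      pseudosession_null(x_list[[i]], y_list[-i], cfg))
    nullm <- do.call(cbind, nulls)
    sig <- significance_per_lag(rho, nullm, cfg)
    out <- c(out, sig, list(null_rho = nullm))
  }
  class(out) <- "coupling_result"
  out
}

#' @export
print.coupling_result <- function(x, ...) {
  cat(sprintf(
    "<coupling_result> %d sessions, lags [%+.0f, %+.0f] s; peak rho = %.3f at %+.1f min\n",
    ncol(x$rho), min(x$lag), max(x$lag), x$peak$value, x$peak$lag / 60))
  if (!is.null(x$flag))
    cat(sprintf("  %d of %d lags significant at BH-adjusted q\n",
                sum(x$flag, na.rm = TRUE), length(x$flag)))
  invisible(x)
}
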