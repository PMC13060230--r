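# Internal numerical helpers shared across the pipeline.

#' @useDynLib glycofp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Causal moving average with expanding warm-up: output at index i is the mean
# of the most recent min(i, w) samples. Keeps the trace length fixed and the
# response stimulus-aligned (no lookahead).
causal_ma <- function(x, w) {
  n <- length(x)
  if (w <= 1L || n == 0L) return(x)
  cs <- cumsum(x)
  i <- seq_len(n)
  lo <- pmax(i - w, 0L)
  (cs - c(0, cs)[lo + 1L]) / (i - lo)
}

# Robust sigma estimate: 1.4826 * median absolute deviation.
mad_sigma <- function(x) {
  stats::mad(x, constant = 1.4826, na.rm = TRUE)
}

# Trapezoidal integral of y over t (same length, t increasing).
trapz <- function(t, y) {
  n <- length(t)
  if (n < 2L) return(0)
  sum(diff(t) * (y[-1L] + y[-n]) / 2)
}

# Index window for t in [lo, hi] (minutes converted by caller to seconds).
which_window <- function(t, lo, hi) {
  which(t >= lo & t <= hi)
}

# First run of at least `len` consecutive TRUE values; returns the index of
# the run start, or NA if none.
first_sustained_run <- function(mask, len) {
  if (!any(mask)) return(NA_integer_)
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= len)
  if (length(hit) == 0L) NA_integer_ else starts[hit[1L]]
}

# Linear interpolation of flagged samples between nearest unflagged
# neighbours; edge flags take the nearest unflagged value.
interp_flagged <- function(x, flagged) {
  if (!any(flagged)) return(x)
  good <- which(!flagged)
  if (length(good) == 0L) stop("all samples flagged; trace unusable")
  x[flagged] <- stats::approx(good, x[good], xout = which(flagged),
                              rule = 2)$y
  x
}
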