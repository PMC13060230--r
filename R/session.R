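#' Construct a recording session
#'
#' A session bundles the two photometry channels (calcium-dependent signal
#' and isosbestic reference) and the arterial glucose trace on one shared,
#' event-anchored 1 Hz grid. Time is stored in seconds relative to the oral
#' gavage (or sham) event, so \code{t = 0} is the event and negative times
#' are baseline.
#'
#' @param subject_id subject identifier (coerced to character).
#' @param dose glucose dose in g per kg body weight; 0 for water.
#' @param t time in seconds relative to the event; strictly increasing with
#'   constant 1 s spacing.
#' @param fp_signal calcium-dependent fluorescence (arbitrary units).
#' @param fp_reference isosbestic fluorescence (arbitrary units).
#' @param glucose arterial glucose (mg/dL).
#' @param session_order ordinal exposure number for the animal (1 = first
#'   gavage that animal received), used by learned-anticipation analyses.
#' @param ground_truth optional list of generator ground-truth components
#'   (only present on synthetic sessions).
#' @return An object of class \code{"fp_session"}.
#' @export
fp_session <- function(subject_id, dose, t, fp_signal, fp_reference,
                       glucose, session_order = NA_integer_,
                       ground_truth = NULL) {
  s <- structure(
    list(subject_id = as.character(subject_id), dose = as.numeric(dose),
         t = as.numeric(t), fp_signal = as.numeric(fp_signal),
         fp_reference = as.numeric(fp_reference),
         glucose = as.numeric(glucose),
         session_order = as.integer(session_order),
         ground_truth = ground_truth),
    class = "fp_session")
  validate_session(s)
  s
}

#' Validate session invariants
#'
#' Checks the structural invariants every downstream stage relies on:
#' strictly increasing time with exact 1 s spacing, matched stream lengths,
#' and a non-negative dose.
#'
#' @param s an \code{fp_session}.
#' @return \code{s}, invisibly; stops with an informative error otherwise.
#' @export
validate_session <- function(s) {
  stopifnot(inherits(s, "fp_session"))
  n <- length(s$t)
  if (n < 2L) stop("session needs at least 2 samples")
  dt <- diff(s$t)
  if (any(dt <= 0)) {
    bad <- which(dt <= 0)[1L]
    stop(sprintf("time axis not strictly increasing at row %d (t = %g)",
                 bad + 1L, s$t[bad + 1L]))
  }
  if (any(abs(dt - 1) > 1e-6)) {
    bad <- which(abs(dt - 1) > 1e-6)[1L]
    stop(sprintf("non-uniform sampling at row %d: spacing %g s (expected 1 s)",
                 bad + 1L, dt[bad]))
  }
  for (f in c("fp_signal", "fp_reference", "glucose")) {
    if (length(s[[f]]) != n)
      stop(sprintf("column %s has length %d, expected %d", f,
                   length(s[[f]]), n))
  }
  if (is.na(s$dose) || s$dose < 0) stop("dose must be non-negative")
  invisible(s)
}

#' @export
print.fp_session <- function(x, ...) {
  cat(sprintf(
    "<fp_session> subject %s, dose %.2g g/kg, t = [%.1f, %.1f] min, %d samples\n",
    x$subject_id, x$dose, min(x$t) / 60, max(x$t) / 60, length(x$t)))
  invisible(x)
}

#' Write a session to disk
#'
#' One CSV per session (columns \code{time_s}, \code{fp_signal},
#' \code{fp_reference}, \code{glucose}) plus a JSON metadata sidecar at
#' \code{<path without .csv>.json} holding \code{subject_id},
#' \code{dose_g_per_kg}, \code{event_time_s} and \code{session_order}.
#'
#' @param s an \code{fp_session}.
#' @param path CSV path to write.
#' @return \code{path}, invisibly.
#' @export
save_session <- function(s, path) {
  validate_session(s)
  df <- data.frame(time_s = s$t, fp_signal = s$fp_signal,
                   fp_reference = s$fp_reference, glucose = s$glucose)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(subject_id = s$subject_id, dose_g_per_kg = s$dose,
               event_time_s = 0, session_order = s$session_order,
               notes = "")
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.csv$", ".json", path)

#' Read a session from disk
#'
#' Reads the per-session CSV and its JSON sidecar and validates the grid.
#' Runs of missing samples (NA) up to \code{max_gap_s} seconds are linearly
#' interpolated with a warning; longer gaps invalidate the session.
#'
#' @param path CSV path written by \code{\link{save_session}} (or any file
#'   with the same columns and a sidecar).
#' @param max_gap_s longest NA run, in seconds, repaired by interpolation.
#' @return An \code{fp_session}.
#' @export
load_session <- function(path, max_gap_s = 5) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path)
  need <- c("time_s", "fp_signal", "fp_reference", "glucose")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop(sprintf("malformed session file %s: missing column(s) %s", path,
                 paste(miss, collapse = ", ")))
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stop(sprintf("metadata sidecar not found: %s", sp))
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  if (anyNA(df$time_s)) stop("column time_s contains missing values")
  for (col in c("fp_signal", "fp_reference", "glucose")) {
    x <- df[[col]]
    if (anyNA(x)) {
      r <- rle(is.na(x))
      if (max(r$lengths[r$values]) > max_gap_s)
        stop(sprintf("column %s has a gap longer than %d s; session invalid",
                     col, max_gap_s))
      warning(sprintf("column %s: %d missing sample(s) linearly interpolated",
                      col, sum(is.na(x))))
      df[[col]] <- interp_flagged(x, is.na(x))
    }
  }
  fp_session(subject_id = meta$subject_id, dose = meta$dose_g_per_kg,
             t = df$time_s - meta$event_time_s, fp_signal = df$fp_signal,
             fp_reference = df$fp_reference, glucose = df$glucose,
             session_order = if (is.null(meta$session_order)) NA_integer_
                             else meta$session_order)
}

#' Align photometry and glucose streams to one event-anchored grid
#'
#' Resamples both acquisition streams (which may start at different clock
#' times and at non-integer phases) onto a shared 1 Hz grid with \code{t = 0}
#' at the event, by linear interpolation. No extrapolation: the grid is
#' limited to the intersection of the two supports.
#'
#' @param fp_t photometry timestamps, seconds (same clock as
#'   \code{event_time}).
#' @param fp two-column matrix (or data.frame) of photometry samples: signal
#'   then reference.
#' @param glu_t glucose timestamps, seconds.
#' @param glu glucose samples, mg/dL.
#' @param event_time event timestamp, seconds, on the shared clock.
#' @param subject_id,dose,session_order session metadata.
#' @param min_overlap_min minimum common span around the event (minutes).
#' @return An \code{fp_session} on the common grid.
#' @export
align_streams <- function(fp_t, fp, glu_t, glu, event_time,
                          subject_id = "s", dose = 0,
                          session_order = NA_integer_,
                          min_overlap_min = 115) {
  fp <- as.matrix(fp)
  stopifnot(ncol(fp) == 2L, length(fp_t) == nrow(fp),
            length(glu_t) == length(glu))
  lo <- max(min(fp_t), min(glu_t))
  hi <- min(max(fp_t), max(glu_t))
  # 1-s slack so sub-second clock offsets at the edges do not disqualify
  if ((hi - lo) < min_overlap_min * 60 - 1)
    stop(sprintf(
      "streams overlap for only %.1f min (need >= %g min); span [%g, %g] s",
      (hi - lo) / 60, min_overlap_min, lo, hi))
  t_grid <- seq(ceiling(lo - event_time), floor(hi - event_time), by = 1)
  abs_t <- t_grid + event_time
  fp_sig <- stats::approx(fp_t, fp[, 1L], xout = abs_t)$y
  fp_ref <- stats::approx(fp_t, fp[, 2L], xout = abs_t)$y
  g <- stats::approx(glu_t, glu, xout = abs_t)$y
  fp_session(subject_id = subject_id, dose = dose, t = t_grid,
             fp_signal = fp_sig, fp_reference = fp_ref, glucose = g,
             session_order = session_order)
}

#' Write / read a cohort manifest
#'
#' The manifest is a CSV listing session file paths with their metadata, the
#' on-disk representation of a cohort.
#'
#' @param sessions list of \code{fp_session}.
#' @param dir directory to write into (created if needed).
#' @return Path to the manifest CSV.
#' @export
save_cohort <- function(sessions, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(length(sessions))
  for (i in seq_along(sessions)) {
    s <- sessions[[i]]
    f <- file.path(dir, sprintf("session_%s_dose%s_%02d.csv", s$subject_id,
                                gsub("[.]", "p", format(s$dose)), i))
    save_session(s, f)
    paths[i] <- f
  }
  man <- data.frame(
    path = paths,
    subject_id = vapply(sessions, `[[`, "", "subject_id"),
    dose = vapply(sessions, `[[`, 0, "dose"),
    session_order = vapply(sessions, function(s) as.integer(s$session_order),
                           integer(1)))
  mf <- file.path(dir, "manifest.csv")
  utils::write.csv(man, mf, row.names = FALSE)
  mf
}

#' @rdname save_cohort
#' @param manifest path to a manifest CSV.
#' @export
load_cohort <- function(manifest) {
  man <- utils::read.csv(manifest)
  lapply(man$path, load_session)
}
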