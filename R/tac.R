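#' Acquisition schedule for a dynamic renography study
#'
#' Describes the frame timing of a dynamic acquisition. Frames must be
#' non-overlapping, with strictly positive durations. Curve values are
#' attached at frame midpoints throughout the package.
#'
#' @param frame_starts Numeric vector of frame start times in seconds,
#'   monotone increasing.
#' @param frame_durations Numeric vector of frame durations in seconds,
#'   same length as `frame_starts`, all `> 0`.
#' @param modality `"mru"` (signal intensity series) or `"drs"`
#'   (gamma-camera counts per frame).
#' @return An object of class `acquisition_schedule`.
#' @seealso [mru_schedule()], [drs_schedule()]
#' @export
acquisition_schedule <- function(frame_starts, frame_durations,
                                 modality = c("mru", "drs")) {
  modality <- match.arg(modality)
  if (length(frame_starts) == 0L)
    stop("schedule must contain at least one frame")
  if (length(frame_starts) != length(frame_durations))
    stop("frame_starts and frame_durations must have equal length")
  if (any(!is.finite(frame_starts)) || any(!is.finite(frame_durations)))
    stop("schedule times must be finite")
  if (any(frame_durations <= 0))
    stop("all frame durations must be > 0")
  if (is.unsorted(frame_starts, strictly = TRUE))
    stop("frame start times must be strictly increasing")
  ends <- frame_starts + frame_durations
  if (length(frame_starts) > 1L &&
      any(frame_starts[-1L] < ends[-length(ends)] - 1e-9))
    stop("frames must not overlap")
  structure(
    list(start = as.numeric(frame_starts),
         duration = as.numeric(frame_durations),
         modality = modality),
    class = "acquisition_schedule"
  )
}

#' Default fMRU dynamic schedule
#'
#' Dual temporal resolution: one frame every 5 s for the first 5 minutes,
#' then one every 30 s for the following 5 minutes (60 + 10 frames,
#' 600 s total).
#' @return An `acquisition_schedule` with `modality = "mru"`.
#' @export
mru_schedule <- function() {
  acquisition_schedule(
    frame_starts = c(seq(0, by = 5, length.out = 60),
                     seq(300, by = 30, length.out = 10)),
    frame_durations = c(rep(5, 60), rep(30, 10)),
    modality = "mru"
  )
}

#' Default DRS schedule
#'
#' 120 frames of 10 s (20 minutes), a typical MAG3 diuretic renography
#' acquisition.
#' @return An `acquisition_schedule` with `modality = "drs"`.
#' @export
drs_schedule <- function() {
  acquisition_schedule(seq(0, by = 10, length.out = 120), rep(10, 120),
                       modality = "drs")
}

#' @export
print.acquisition_schedule <- function(x, ...) {
  cat(sprintf("<acquisition_schedule> %s, %d frames, span %.0f-%.0f s\n",
              x$modality, length(x$start), x$start[1L],
              x$start[length(x$start)] + x$duration[length(x$duration)]))
  invisible(x)
}

#' Frame midpoints of a schedule
#' @param schedule An `acquisition_schedule`.
#' @return Numeric vector of frame midpoint times in seconds.
#' @export
schedule_midpoints <- function(schedule) schedule$start + schedule$duration / 2

#' Number of frames in a schedule
#' @param schedule An `acquisition_schedule`.
#' @return Integer frame count.
#' @export
n_frames <- function(schedule) length(schedule$start)

#' Time-activity curve
#'
#' One region's signal (fMRU, arbitrary units) or count (DRS, counts/frame)
#' trace over a dynamic acquisition, sampled at frame midpoints.
#'
#' @param time Numeric vector of frame midpoint times, seconds, strictly
#'   increasing.
#' @param duration Numeric vector of frame durations, seconds.
#' @param value Numeric vector of curve values, same length, all finite.
#' @param label Region label (e.g. `"left_kidney"`).
#' @param modality `"mru"` or `"drs"`.
#' @param flags Optional character vector of QC flags.
#' @return An object of class `tac`.
#' @export
tac <- function(time, duration, value, label = "", modality = c("mru", "drs"),
                flags = character()) {
  modality <- match.arg(modality)
  n <- length(time)
  if (n == 0L) stop("empty curve")
  if (length(duration) == 1L) duration <- rep(duration, n)
  if (length(value) != n || length(duration) != n)
    stop("time, duration and value must have equal length")
  if (any(!is.finite(value))) stop("curve values must be finite")
  if (is.unsorted(time, strictly = TRUE))
    stop("curve times must be strictly increasing")
  structure(
    list(time = as.numeric(time), duration = as.numeric(duration),
         value = as.numeric(value), label = label, modality = modality,
         flags = flags),
    class = "tac"
  )
}

#' Build a curve on a schedule
#' @param schedule An `acquisition_schedule`.
#' @param values Numeric vector, one value per frame.
#' @param label Region label.
#' @param flags Optional QC flags.
#' @return A [tac()].
#' @export
tac_from_schedule <- function(schedule, values, label = "",
                              flags = character()) {
  tac(schedule_midpoints(schedule), schedule$duration, values,
      label = label, modality = schedule$modality, flags = flags)
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf(
    "<tac> %s [%s], %d frames, t = %.1f-%.1f s, value range [%.4g, %.4g]\n",
    if (nzchar(x$label)) x$label else "(unlabeled)", x$modality,
    length(x$time), min(x$time), max(x$time), min(x$value), max(x$value)))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.tac <- function(x, ...) {
  data.frame(time_s = x$time, duration_s = x$duration, value = x$value)
}

#' Linear interpolation of a curve at arbitrary times
#'
#' Constant extrapolation at the ends (rule = 2).
#' @param curve A [tac()].
#' @param t Times (s) at which to evaluate.
#' @return Numeric vector of interpolated values.
#' @export
tac_at <- function(curve, t) {
  stats::approx(curve$time, curve$value, xout = t, rule = 2)$y
}

#' Exact integral of the piecewise-linear curve over a window
#'
#' Integrates the linear interpolant of the sampled curve; window endpoints
#' falling between samples are handled by interpolation, so the result is
#' the exact trapezoid integral of the interpolant over `window`.
#'
#' @param curve A [tac()].
#' @param window Length-2 numeric `[t1, t2]` in seconds, or `NULL` for the
#'   full span.
#' @return The integral (value units x seconds).
#' @export
tac_integral <- function(curve, window = NULL) {
  t <- curve$time; v <- curve$value
  if (is.null(window)) window <- range(t)
  if (length(window) != 2L || window[2] <= window[1])
    stop("window must be [t1, t2] with t1 < t2")
  w1 <- max(window[1], t[1L]); w2 <- min(window[2], t[length(t)])
  if (w2 <= w1) return(0)
  inner <- t > w1 & t < w2
  tt <- c(w1, t[inner], w2)
  vv <- c(tac_at(curve, w1), v[inner], tac_at(curve, w2))
  pracma::trapz(tt, vv)
}

#' Running integral of a curve from time zero
#'
#' Cumulative trapezoid integral of the curve, assuming the signal is zero
#' at t = 0 and rises linearly to the first sample (the pre-bolus baseline
#' of a dynamic study).
#'
#' @param curve A [tac()].
#' @return Numeric vector: the running integral at each frame midpoint.
#' @export
tac_cumulative <- function(curve) {
  t <- c(0, curve$time); v <- c(0, curve$value)
  if (curve$time[1L] <= 0) { t <- curve$time; v <- curve$value }
  ci <- as.numeric(pracma::cumtrapz(t, v))
  if (length(ci) > length(curve$time)) ci <- ci[-1L]
  ci
}

#' Read a curve from CSV
#'
#' Dialect: header `time_s,duration_s,value`, UTF-8, '.' decimal separator.
#' @param path File path.
#' @param label Region label to attach.
#' @param modality `"mru"` or `"drs"`.
#' @return A [tac()].
#' @export
read_tac <- function(path, label = "", modality = c("mru", "drs")) {
  d <- utils::read.csv(path)
  need <- c("time_s", "duration_s", "value")
  if (!all(need %in% names(d)))
    stop("curve CSV must have columns time_s,duration_s,value")
  tac(d$time_s, d$duration_s, d$value, label = label,
      modality = match.arg(modality))
}

#' Write a curve to CSV
#' @param curve A [tac()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tac <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
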