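#' Extract a region's time-activity curve from a dynamic series
#'
#' fMRU curves are per-frame ROI means (signal intensity is intensive);
#' DRS curves are per-frame ROI sums (counts are extensive). The
#' normalization cancels in every downstream left/right ratio.
#'
#' @param series A `phantom_study`, or a raw array whose last dimension is
#'   time (then `schedule` is required).
#' @param mask A [region_mask()] on the series' spatial grid.
#' @param schedule Required when `series` is a raw array.
#' @param modality Overrides the modality when `series` is a raw array;
#'   defaults to the schedule's.
#' @return A [tac()].
#' @export
extract_curve <- function(series, mask, schedule = NULL, modality = NULL) {
  if (inherits(series, "phantom_study")) {
    schedule <- series$schedule
    modality <- series$modality
    series <- series$data
  }
  if (is.null(schedule)) stop("schedule required for raw array input")
  if (is.null(modality)) modality <- schedule$modality
  if (!inherits(mask, "region_mask") || length(mask$indices) == 0L)
    stop("mask must be a non-empty region_mask")
  d <- dim(series)
  n_sp <- prod(d[-length(d)])
  nf <- d[length(d)]
  if (nf != n_frames(schedule))
    stop("series frame count does not match schedule")
  if (max(mask$indices) > n_sp || min(mask$indices) < 1L)
    stop("mask indices outside the series grid")
  m <- matrix(series, nrow = n_sp, ncol = nf)[mask$indices, , drop = FALSE]
  vals <- if (modality == "drs") colSums(m) else colMeans(m)
  tac_from_schedule(schedule, vals, label = mask$label)
}

#' Background-correct a kidney curve
#'
#' `corrected(t) = kidney(t) - size_ratio * background(t)`. For DRS count
#' curves the conventional scaling is the kidney/background ROI size ratio
#' (counts are extensive); for fMRU signal means the background is
#' subtracted unscaled (`size_ratio = 1`). Negative corrected values are
#' clipped to zero; the clip count is recorded in the result's flags and
#' in attribute `n_clipped`.
#'
#' @param kidney,background [tac()] objects on the same schedule.
#' @param size_ratio Kidney-to-background ROI size ratio; default 1.
#' @return A corrected [tac()].
#' @export
background_subtract <- function(kidney, background, size_ratio = 1) {
  if (length(kidney$time) != length(background$time) ||
      max(abs(kidney$time - background$time)) > 1e-9)
    stop("kidney and background curves must share a schedule")
  v <- kidney$value - size_ratio * background$value
  n_clip <- sum(v < 0)
  flags <- kidney$flags
  if (n_clip > 0)
    flags <- c(flags, sprintf("clipped %d negative frames", n_clip))
  out <- tac(kidney$time, kidney$duration, pmax(v, 0),
             label = kidney$label, modality = kidney$modality,
             flags = flags)
  attr(out, "n_clipped") <- n_clip
  out
}

#' Resample a curve on a uniform grid
#'
#' Linear interpolation on the uniform grid covering the original span;
#' both endpoints are kept exactly (the final step may be shorter than
#' `dt`). Needed because the fMRU schedule changes frame rate after
#' 5 minutes.
#'
#' @param curve A [tac()] with at least 2 frames.
#' @param dt Target sampling interval, s, `> 0`.
#' @return A resampled [tac()].
#' @export
resample_uniform <- function(curve, dt) {
  if (dt <= 0) stop("dt must be > 0")
  if (length(curve$time) < 2L) stop("need at least 2 frames to resample")
  t1 <- curve$time[1L]; t2 <- curve$time[length(curve$time)]
  grid <- seq(t1, t2, by = dt)
  if (grid[length(grid)] < t2 - 1e-9) grid <- c(grid, t2)
  v <- stats::approx(curve$time, curve$value, xout = grid)$y
  dur <- c(diff(grid), dt)
  tac(grid, dur, v, label = curve$label, modality = curve$modality,
      flags = curve$flags)
}

# centered moving average with window shrinking at the edges
moving_average <- function(v, window) {
  h <- (window - 1L) %/% 2L
  if (h == 0L) return(v)
  n <- length(v)
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Locate the filtration peak of a curve
#'
#' Global maximum of the moving-average smoothed curve, ties broken toward
#' the earliest frame. A flat curve returns the first frame with a
#' `"flat curve"` flag.
#'
#' @param curve A [tac()].
#' @param smooth_window Moving-average window in frames, odd, `>= 1`.
#' @return A list with `t_peak` (s), `value` (smoothed peak value),
#'   `index`, and `flags`.
#' @export
find_peak <- function(curve, smooth_window = 5) {
  if (smooth_window < 1 || smooth_window %% 2 == 0)
    stop("smooth_window must be odd and >= 1")
  s <- moving_average(curve$value, smooth_window)
  flags <- character()
  if (max(s) - min(s) <= 0) {
    flags <- "flat curve"
    i <- 1L
  } else {
    i <- which.max(s)   # which.max takes the earliest tie
  }
  list(t_peak = curve$time[i], value = s[i], index = i, flags = flags)
}
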