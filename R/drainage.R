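#' Classify a drainage curve into the three canonical patterns
#'
#' Operationalization of the visual three-pattern reading of diuretic
#' renography drainage curves (after O'Reilly): let `t_peak` be the
#' smoothed global maximum and `r` the mean of the final `end_window`
#' seconds divided by the peak value. The curve is
#' * `"accumulation"` if `t_peak` falls within the final `end_window`
#'   (signal still rising at study end);
#' * `"normal"` if `r <= 1 - decline_threshold` (clear post-peak decline);
#' * `"borderline"` otherwise (post-peak plateau).
#'
#' Thresholds are configurable: the pattern boundaries are genuinely
#' ambiguous in clinical reading (inter-reader kappa near 0.56), so no
#' single rule is canonical.
#'
#' @param curve A [tac()] over kidney + collecting system, spanning at
#'   least `2 * end_window`.
#' @param decline_threshold Required fractional decline from peak for a
#'   normal pattern, in (0, 1). Default 0.10.
#' @param end_window Length of the terminal evaluation window, s.
#'   Default 60.
#' @param smooth_window Moving-average window (frames) for peak finding.
#' @return Character pattern, with attributes `r` (end/peak ratio),
#'   `t_peak`, and `flags`.
#' @export
classify_drainage <- function(curve, decline_threshold = 0.10,
                              end_window = 60, smooth_window = 5) {
  if (decline_threshold <= 0 || decline_threshold >= 1)
    stop("decline_threshold must be in (0, 1)")
  span <- max(curve$time) - min(curve$time)
  if (span < 2 * end_window)
    stop("curve must span at least twice the end window")
  if (all(curve$value == 0)) stop("all-zero curve cannot be classified")
  pk <- find_peak(curve, smooth_window)
  flags <- pk$flags
  if ("flat curve" %in% flags) {
    out <- "borderline"
    attr(out, "r") <- 1
    attr(out, "t_peak") <- pk$t_peak
    attr(out, "flags") <- flags
    return(out)
  }
  s <- moving_average(curve$value, smooth_window)
  late <- curve$time >= max(curve$time) - end_window
  r <- mean(s[late]) / pk$value
  out <- if (pk$t_peak >= max(curve$time) - end_window) "accumulation"
  else if (r <= 1 - decline_threshold) "normal"
  else "borderline"
  attr(out, "r") <- r
  attr(out, "t_peak") <- pk$t_peak
  attr(out, "flags") <- flags
  out
}

#' Normalized residual activity (NORA)
#'
#' Late residual activity relative to early uptake:
#' `NORA = value(t_eval) / mean(ref_window)`. By nuclear-medicine
#' convention the reference window is 1-2 min after injection and the
#' evaluation point 20 min (or the end of a shorter study). Values above 1
#' indicate retention.
#'
#' @param curve A [tac()].
#' @param t_eval Evaluation time, s; default `min(1200, end of study)`.
#' @param ref_window Reference window `[t1, t2]`, s. Default `c(60, 120)`.
#' @return NORA, dimensionless.
#' @export
nora <- function(curve, t_eval = NULL, ref_window = c(60, 120)) {
  t_end <- max(curve$time)
  if (is.null(t_eval)) t_eval <- min(1200, t_end)
  if (t_eval > t_end + 1e-9 || t_eval < min(curve$time))
    stop("t_eval outside the curve span")
  if (ref_window[1] >= ref_window[2])
    stop("ref_window must be [t1, t2] with t1 < t2")
  ref <- tac_integral(curve, ref_window) / diff(ref_window)
  if (ref <= 0) stop("zero reference activity: NORA undefined")
  tac_at(curve, t_eval) / ref
}

#' Renal output efficiency (ROE)
#'
#' Fraction of the tracer delivered to the kidney that has left it by
#' `t_eval`. The expected cumulative input is taken from the
#' Rutland-Patlak model, \eqn{U(t) = K \int_0^{t} P\,ds}: the residual the
#' kidney would hold had nothing drained. Then
#' `ROE = 100 * (1 - R(t_eval) / U(t_eval))`, clipped at 100; negative
#' values (residual exceeding modelled input, e.g. vascular signal on top
#' of full retention) are flagged, not clipped.
#'
#' @param curve Whole-kidney [tac()] (same units as the Patlak fit's
#'   renal curve).
#' @param fit A [patlak_fit()] for the same kidney with `slope_K > 0`.
#' @param aorta Input [tac()] used for the fit.
#' @param t_eval Evaluation time, s; default end of study.
#' @return ROE in percent, with attribute `flags`.
#' @export
output_efficiency <- function(curve, fit, aorta, t_eval = NULL) {
  if (fit$slope_K <= 0) stop("output efficiency requires a positive K")
  t_end <- max(curve$time)
  if (is.null(t_eval)) t_eval <- t_end
  if (t_eval > t_end + 1e-9) stop("t_eval outside the curve span")
  cumP <- tac_cumulative(aorta)
  u <- fit$slope_K *
    stats::approx(aorta$time, cumP, xout = t_eval, rule = 2)$y
  if (u <= 0) stop("non-positive modelled input: ROE undefined")
  roe <- 100 * (1 - tac_at(curve, t_eval) / u)
  flags <- character()
  if (roe < 0) flags <- "residual exceeds modelled input"
  roe <- min(roe, 100)
  attr(roe, "flags") <- flags
  roe
}

#' Time of the renogram maximum (Tmax)
#'
#' Delegates to [find_peak()]; a peak on the final frame is flagged
#' `"no peak"` (curve still rising at study end).
#'
#' @param curve A [tac()].
#' @param smooth_window Moving-average window, frames.
#' @return Tmax in seconds, with attribute `flags`.
#' @export
tmax <- function(curve, smooth_window = 5) {
  pk <- find_peak(curve, smooth_window)
  flags <- pk$flags
  if (pk$index == length(curve$time)) flags <- c(flags, "no peak")
  out <- pk$t_peak
  attr(out, "flags") <- flags
  out
}

#' Full drainage assessment of one kidney curve
#'
#' Bundles the three-pattern classification with the quantitative drainage
#' metrics (Tmax, NORA, output efficiency when a Patlak fit is supplied).
#'
#' @param curve Whole kidney + pelvis [tac()].
#' @param fit Optional [patlak_fit()] for ROE.
#' @param aorta Optional input [tac()] for ROE.
#' @param decline_threshold,end_window See [classify_drainage()].
#' @return An object of class `drainage_result`: `pattern`, `t_max`,
#'   `nora`, `roe` (`NA` without a fit), `end_to_peak_ratio`, `flags`.
#' @export
assess_drainage <- function(curve, fit = NULL, aorta = NULL,
                            decline_threshold = 0.10, end_window = 60) {
  pattern <- classify_drainage(curve, decline_threshold, end_window)
  tm <- tmax(curve)
  nr <- nora(curve)
  roe <- NA_real_
  flags <- c(attr(pattern, "flags"), attr(tm, "flags"))
  if (!is.null(fit) && !is.null(aorta) && fit$slope_K > 0) {
    roe <- output_efficiency(curve, fit, aorta)
    flags <- c(flags, attr(roe, "flags"))
    roe <- as.numeric(roe)
  }
  structure(
    list(pattern = as.character(pattern), t_max = as.numeric(tm),
         nora = nr, roe = roe,
         end_to_peak_ratio = attr(pattern, "r"), flags = flags),
    class = "drainage_result"
  )
}

#' @export
print.drainage_result <- function(x, ...) {
  cat(sprintf(
    "<drainage_result> %s: Tmax %.0f s, NORA %.2f, ROE %s, end/peak %.2f\n",
    x$pattern, x$t_max, x$nora,
    if (is.na(x$roe)) "NA" else sprintf("%.1f%%", x$roe),
    x$end_to_peak_ratio))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
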