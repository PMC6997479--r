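normalize_pair <- function(a, b, what = "SRF") {
  if (!is.finite(a) || !is.finite(b) || a + b <= 0)
    stop(sprintf("undefined %s: non-positive left+right total", what))
  p <- 100 * c(a, b) / (a + b)
  names(p) <- c("left", "right")
  p
}

#' Split renal function by the area-under-the-curve method
#'
#' Integrates the two background-corrected parenchymal curves over the
#' uptake window and returns the left/right percentage split
#' `100 * A_L / (A_L + A_R)` (pair sums to 100 exactly).
#'
#' @param left,right Background-corrected [tac()] curves on the same
#'   schedule.
#' @param window Length-2 numeric `[t1, t2]` in seconds; should end before
#'   collecting-system outflow begins.
#' @return Named numeric `c(left =, right =)` in percent.
#' @export
auc_srf <- function(left, right, window) {
  if (length(left$time) != length(right$time) ||
      max(abs(left$time - right$time)) > 1e-9)
    stop("left and right curves must share a schedule")
  a_l <- tac_integral(left, window)
  a_r <- tac_integral(right, window)
  normalize_pair(a_l, a_r)
}

#' Rutland-Patlak fit of one kidney against the aortic input
#'
#' Ordinary least squares of the linearized irreversible-uptake model
#' \deqn{\frac{Q(t)}{P(t)} = K \frac{\int_0^t P\,d\tau}{P(t)} + V_0}
#' over the frames inside `window`. The running aortic integral is the
#' trapezoid cumulative from t = 0. Frames with non-positive aortic values
#' are dropped with a warning; at least 3 usable frames are required.
#'
#' @param renal Kidney [tac()] (parenchymal ROI for fMRU, whole-kidney
#'   background-corrected counts for DRS).
#' @param aorta Input-function [tac()] on the same schedule.
#' @param window Length-2 fit window `[t_start, t_end]`, s, inside the
#'   uptake phase.
#' @return An object of class `patlak_fit`: `slope_K`, `intercept_V0`,
#'   `r_squared`, `window`, `n_points`, `n_dropped`.
#' @export
patlak_fit <- function(renal, aorta, window) {
  if (length(renal$time) != length(aorta$time) ||
      max(abs(renal$time - aorta$time)) > 1e-9)
    stop("renal and aortic curves must share a schedule")
  if (length(window) != 2L || window[2] <= window[1])
    stop("window must be [t_start, t_end] with t_start < t_end")
  cumP <- tac_cumulative(aorta)
  sel <- renal$time >= window[1] & renal$time <= window[2]
  if (!any(sel)) stop("no frames inside the fit window")
  usable <- sel & aorta$value > 0
  n_dropped <- sum(sel) - sum(usable)
  if (n_dropped > 0)
    warning(sprintf("dropped %d frames with non-positive input", n_dropped))
  if (sum(usable) < 3L)
    stop("fewer than 3 usable frames for the Patlak fit")
  x <- cumP[usable] / aorta$value[usable]
  y <- renal$value[usable] / aorta$value[usable]
  fit <- stats::lm(y ~ x)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) max(0, min(1, 1 - sum(stats::resid(fit)^2) / sst)) else 1
  structure(
    list(slope_K = unname(stats::coef(fit)[2L]),
         intercept_V0 = unname(stats::coef(fit)[1L]),
         r_squared = r2,
         window = as.numeric(window),
         n_points = sum(usable), n_dropped = n_dropped),
    class = "patlak_fit"
  )
}

#' @export
print.patlak_fit <- function(x, ...) {
  cat(sprintf(
    "<patlak_fit> K = %.5g /s, V0 = %.4g, r^2 = %.4f, window %.0f-%.0f s (%d pts)\n",
    x$slope_K, x$intercept_V0, x$r_squared, x$window[1], x$window[2],
    x$n_points))
  invisible(x)
}

#' Split renal function from a pair of Patlak fits
#'
#' Non-physical negative slopes are floored at zero with a warning before
#' forming `100 * K_L / (K_L + K_R)`.
#'
#' @param fit_left,fit_right [patlak_fit()] objects.
#' @return Named numeric `c(left =, right =)` in percent.
#' @export
patlak_srf <- function(fit_left, fit_right) {
  k <- c(fit_left$slope_K, fit_right$slope_K)
  if (any(!is.finite(k))) stop("Patlak slopes must be finite")
  if (any(k < 0)) {
    warning("negative Patlak slope floored at 0")
    k <- pmax(k, 0)
  }
  normalize_pair(k[1], k[2])
}

# 26-connected components of a logical 3D array via igraph.
# Returns integer array of component labels (0 = background).
connected_components_3d <- function(fg) {
  d <- dim(fg)
  ids <- array(0L, d)
  ids[fg] <- seq_len(sum(fg))
  offsets <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offsets <- offsets[rowSums(abs(offsets)) > 0, ]
  # half of the 26 neighbours is enough for an undirected graph
  offsets <- offsets[seq_len(13), ]
  edges <- vector("list", 13)
  for (r in seq_len(13)) {
    dx <- offsets$dx[r]; dy <- offsets$dy[r]; dz <- offsets$dz[r]
    xs <- max(1, 1 + dx):min(d[1], d[1] + dx)
    ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
    zs <- max(1, 1 + dz):min(d[3], d[3] + dz)
    a <- ids[xs, ys, zs, drop = FALSE]
    b <- ids[xs - dx, ys - dy, zs - dz, drop = FALSE]
    keep <- a > 0L & b > 0L
    edges[[r]] <- cbind(a[keep], b[keep])
  }
  e <- do.call(rbind, edges)
  if (is.null(e) || nrow(e) == 0L) {
    comp <- seq_len(sum(fg))
  } else {
    g <- igraph::graph_from_edgelist(e, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, sum(fg) - igraph::vcount(g)))
    comp <- igraph::components(g)$membership
  }
  out <- array(0L, d)
  out[fg] <- comp[ids[fg]]
  out
}

#' Segment kidney volumes by thresholding and connected components
#'
#' Binarizes the volume at `threshold_fraction` of its maximum, keeps the
#' two largest 26-connected components and assigns them to left/right by
#' centroid (the first array axis increases toward the patient's left).
#' A deliberately simple stand-in for a dedicated parenchymal segmentation
#' algorithm, sufficient for phantom geometry.
#'
#' @param volume_frame 3D numeric array (e.g. the structural volume of a
#'   simulated study).
#' @param threshold_fraction Fraction of the frame maximum in (0, 1).
#' @param voxel_volume Voxel volume, mm^3.
#' @return A list with `volume_left`, `volume_right` (mL; `NA` for a
#'   missing side), `n_components`, `voxels_left`, `voxels_right`, and
#'   `flags`.
#' @export
segment_volume <- function(volume_frame, threshold_fraction = 0.5,
                           voxel_volume) {
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("threshold_fraction must be in (0, 1)")
  mx <- max(volume_frame)
  fg <- volume_frame >= threshold_fraction * mx
  if (mx <= 0 || sum(fg) == 0L)
    stop("empty frame: nothing above threshold")
  comp <- connected_components_3d(fg)
  sizes <- tabulate(comp[comp > 0L])
  ord <- order(sizes, decreasing = TRUE)
  d <- dim(volume_frame)
  centroid_x <- function(k) mean(arrayInd(which(comp == k), d)[, 1L])
  mid <- (d[1L] + 1) / 2
  res <- list(volume_left = NA_real_, volume_right = NA_real_,
              n_components = length(sizes),
              voxels_left = NA_integer_, voxels_right = NA_integer_,
              flags = character())
  if (length(sizes) == 1L) {
    side <- if (centroid_x(ord[1L]) >= mid) "left" else "right"
    res[[paste0("volume_", side)]] <- sizes[ord[1L]] * voxel_volume / 1000
    res[[paste0("voxels_", side)]] <- sizes[ord[1L]]
    res$flags <- sprintf("single component: %s side missing",
                         setdiff(c("left", "right"), side))
    return(res)
  }
  top <- ord[1:2]
  cx <- vapply(top, centroid_x, numeric(1))
  left_k <- top[which.max(cx)]
  right_k <- top[which.min(cx)]
  res$volume_left <- sizes[left_k] * voxel_volume / 1000
  res$volume_right <- sizes[right_k] * voxel_volume / 1000
  res$voxels_left <- sizes[left_k]
  res$voxels_right <- sizes[right_k]
  res
}

#' Volumetric split renal function
#'
#' Combines per-unit-volume uptake indices (Patlak slope density, or an
#' AUC-based index used identically) with segmented parenchymal volumes:
#' \deqn{vSRF_L = 100 \frac{V_L k_L}{V_L k_L + V_R k_R}}
#'
#' @param k_left,k_right Per-unit-volume functional indices (1/s per mL of
#'   ROI, or any common positive scale).
#' @param volume_left,volume_right Parenchymal volumes, mL, `> 0`.
#' @return Named numeric `c(left =, right =)` in percent.
#' @export
volumetric_srf <- function(k_left, k_right, volume_left, volume_right) {
  if (volume_left <= 0 || volume_right <= 0) stop("volumes must be > 0")
  normalize_pair(volume_left * k_left, volume_right * k_right,
                 what = "volumetric SRF")
}
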