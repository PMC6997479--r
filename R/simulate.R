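#' Region mask on a series grid
#'
#' @param label Region label, one of `"left_kidney"`, `"right_kidney"`,
#'   `"left_pelvis"`, `"right_pelvis"`, `"left_drainage"`,
#'   `"right_drainage"`, `"aorta"`, `"heart"`, `"background"`,
#'   `"left_background"`, `"right_background"`.
#' @param indices Integer vector of linear indices into the spatial grid
#'   (the first `length(dim) - 1` dimensions of the series array).
#' @param element_size Element size: mm^3 for voxels, mm^2 for pixels.
#' @return An object of class `region_mask`.
#' @export
region_mask <- function(label, indices, element_size) {
  if (length(indices) == 0L) stop("mask must be non-empty")
  structure(list(label = label, indices = as.integer(indices),
                 element_size = element_size),
            class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask> %s: %d elements, element size %.2f\n",
              x$label, length(x$indices), x$element_size))
  invisible(x)
}

#' Voxelized axis-aligned ellipsoid
#'
#' @param dim Integer length-3 grid dimensions.
#' @param spacing Numeric length-3 voxel spacing, mm.
#' @param center Ellipsoid centre in mm (grid centred at the origin).
#' @param semiaxes Numeric length-3 semi-axes, mm.
#' @return Logical array: voxel centres inside the ellipsoid.
#' @export
ellipsoid_mask <- function(dim, spacing, center, semiaxes) {
  ax <- (seq_len(dim[1]) - (dim[1] + 1) / 2) * spacing[1]
  ay <- (seq_len(dim[2]) - (dim[2] + 1) / 2) * spacing[2]
  az <- (seq_len(dim[3]) - (dim[3] + 1) / 2) * spacing[3]
  dx2 <- ((ax - center[1]) / semiaxes[1])^2
  dy2 <- ((ay - center[2]) / semiaxes[2])^2
  dz2 <- ((az - center[3]) / semiaxes[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
}

# Semi-axis a for an ellipsoid with semi-axes (a, a, 2a) and volume V (mL):
# V_mm3 = (4/3) pi a^2 (2a) = (8/3) pi a^3
kidney_semiaxis <- function(volume_ml) (3 * volume_ml * 1000 / (8 * pi))^(1 / 3)

# 2D ellipse / disc masks on a pixel grid centred at the origin
ellipse_mask2d <- function(dim, spacing, center, semiaxes) {
  ax <- (seq_len(dim[1]) - (dim[1] + 1) / 2) * spacing
  az <- (seq_len(dim[2]) - (dim[2] + 1) / 2) * spacing
  outer(((ax - center[1]) / semiaxes[1])^2,
        ((az - center[2]) / semiaxes[2])^2, `+`) <= 1
}

# C-shaped perirenal band: normalized elliptical radius in (1.15, 1.5],
# open toward the midline (|angle from lateral axis| <= 120 degrees kept).
c_background_mask2d <- function(dim, spacing, center, semiaxes, side) {
  ax <- (seq_len(dim[1]) - (dim[1] + 1) / 2) * spacing
  az <- (seq_len(dim[2]) - (dim[2] + 1) / 2) * spacing
  nx <- outer((ax - center[1]) / semiaxes[1], rep(1, dim[2]))
  nz <- outer(rep(1, dim[1]), (az - center[2]) / semiaxes[2])
  r <- sqrt(nx^2 + nz^2)
  lateral <- if (side == "left") nx else -nx   # +x is the patient's left
  ang <- atan2(nz, lateral)
  r > 1.15 & r <= 1.5 & abs(ang) <= 2 * pi / 3
}

add_trace <- function(arr_flat, n_spatial, idx, trace) {
  # adds trace[f] to arr[idx, f] for all frames; arr_flat is modified copy
  nf <- length(trace)
  pos <- rep(idx, times = nf) + rep(0:(nf - 1), each = length(idx)) * n_spatial
  arr_flat[pos] <- arr_flat[pos] + rep(trace, each = length(idx))
  arr_flat
}

#' Simulate a complete dynamic renography study
#'
#' Generates either a 4D fMRU study (two ellipsoidal kidneys with medial
#' pelvic reservoirs and an aortic tube on a labelled voxel grid, additive
#' Gaussian noise) or a 2D posterior-projection DRS study (projected kidney
#' and pelvis regions, cardiac blood-pool disc, C-shaped perirenal
#' background, Poisson counts). The ground truth is recorded before noise
#' is added and the whole study is reproducible from `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @param modality `"mru"` or `"drs"`.
#' @param noise If `FALSE`, return noise-free expected values (the Poisson
#'   means for DRS).
#' @param schedule Optional [acquisition_schedule()]; defaults to
#'   [mru_schedule()] / [drs_schedule()].
#' @param spacing fMRU voxel spacing, mm (default in-plane 2 mm, slice
#'   thickness 4 mm, gap zero).
#' @param pixel_mm DRS pixel size, mm.
#' @return An object of class `phantom_study`: a list with elements
#'   `modality`, `data` (4D array x,y,z,t for mru; 3D array x,z,t for drs),
#'   `structural` (mru only: 3D volume for segmentation), `labels`,
#'   `masks` (named list of [region_mask()]), `schedule`, `spacing` or
#'   `pixel_mm`, `aif` (noise-free input [tac()]), `truth`
#'   ([phantom_truth()]) and `spec`.
#' @export
simulate_study <- function(spec, modality = c("mru", "drs"), noise = TRUE,
                           schedule = NULL, spacing = c(2, 2, 4),
                           pixel_mm = 4) {
  modality <- match.arg(modality)
  set.seed(spec$seed)
  if (is.null(schedule))
    schedule <- if (modality == "mru") mru_schedule() else drs_schedule()
  aif <- aortic_input(schedule, peak_time = spec$bolus_peak_time,
                      shape_alpha = spec$bolus_alpha,
                      scale_beta = spec$bolus_beta,
                      recirculation_fraction = spec$recirculation_fraction)
  left <- renal_curve(spec, "left", aif)
  right <- renal_curve(spec, "right", aif)
  truth <- phantom_truth(spec)
  if (modality == "mru") {
    sim_mru(spec, schedule, aif, left, right, truth, spacing, noise)
  } else {
    sim_drs(spec, schedule, aif, left, right, truth, pixel_mm, noise)
  }
}

sim_mru <- function(spec, schedule, aif, left, right, truth, spacing,
                    noise) {
  a_l <- kidney_semiaxis(spec$volume_left)
  a_r <- kidney_semiaxis(spec$volume_right)
  a_max <- max(a_l, a_r)
  pelv_r <- 11                      # ~5.6 mL pelvic reservoir
  gap <- 24                         # kidney-midline clearance, mm
  cx_l <- a_l + gap; cx_r <- -(a_r + gap)
  fov_x <- 2 * (a_max + gap + a_max + 10)
  dim3 <- c(ceiling(fov_x / spacing[1] / 2) * 2,
            ceiling((2 * a_max + 16) / spacing[2] / 2) * 2,
            ceiling((4 * a_max + 16) / spacing[3] / 2) * 2)
  if (any(dim3 < 4) || prod(dim3) > 5e6)
    stop("kidney volumes incompatible with the simulation grid")
  lab <- array(0L, dim3)
  aorta <- ellipsoid_mask(dim3, spacing, c(0, 0, 0),
                          c(7, 7, 1e6))               # vertical cylinder
  lab[aorta] <- 5L
  kid_l <- ellipsoid_mask(dim3, spacing, c(cx_l, 0, 0), c(a_l, a_l, 2 * a_l))
  kid_r <- ellipsoid_mask(dim3, spacing, c(cx_r, 0, 0), c(a_r, a_r, 2 * a_r))
  lab[kid_l & lab == 0L] <- 1L
  lab[kid_r & lab == 0L] <- 2L
  pel_l <- ellipsoid_mask(dim3, spacing, c(cx_l - a_l - 8, 0, -a_l),
                          rep(pelv_r, 3))
  pel_r <- ellipsoid_mask(dim3, spacing, c(cx_r + a_r + 8, 0, -a_r),
                          rep(pelv_r, 3))
  lab[pel_l & lab == 0L] <- 3L
  lab[pel_r & lab == 0L] <- 4L
  vox_ml <- prod(spacing) / 1000
  n_sp <- prod(dim3)
  idx <- lapply(1:5, function(k) which(lab == k))
  nf <- n_frames(schedule)

  # voxel traces: parenchyma carries the intensive signal; the pelvis voxel
  # signal is the pelvic amount divided by the discretized pelvis volume,
  # so ROI sums remain proportional to parenchyma + pelvis amounts.
  p_l <- attr(left, "parenchyma"); v_l <- attr(left, "pelvis")
  p_r <- attr(right, "parenchyma"); v_r <- attr(right, "pelvis")
  scale_l <- spec$volume_left / (length(idx[[1]]) * vox_ml)
  scale_r <- spec$volume_right / (length(idx[[2]]) * vox_ml)
  traces <- list(p_l * scale_l, p_r * scale_r,
                 v_l * spec$volume_left / (length(idx[[3]]) * vox_ml),
                 v_r * spec$volume_right / (length(idx[[4]]) * vox_ml),
                 aif$value)
  sd <- spec$mru_noise_sd
  if (is.null(sd)) sd <- 0.01 * max(p_l * scale_l, p_r * scale_r)
  flat <- if (noise && sd > 0) stats::rnorm(n_sp * nf, 0, sd) else
    numeric(n_sp * nf)
  for (k in 1:5) flat <- add_trace(flat, n_sp, idx[[k]], traces[[k]])
  dyn <- array(flat, c(dim3, nf))

  struct_v <- c(1, 1, 0.35, 0.35, 0.2)   # parenchyma-bright contrast
  structural <- array(0, dim3)
  for (k in 1:5) structural[idx[[k]]] <- struct_v[k]
  if (noise) structural <- structural + stats::rnorm(n_sp, 0, 0.02)

  bg_band <- which(lab == 0L &
                     slice.index(lab, 1) <= max(3L, dim3[1] %/% 20L))
  masks <- list(
    left_kidney = region_mask("left_kidney", idx[[1]], prod(spacing)),
    right_kidney = region_mask("right_kidney", idx[[2]], prod(spacing)),
    left_pelvis = region_mask("left_pelvis", idx[[3]], prod(spacing)),
    right_pelvis = region_mask("right_pelvis", idx[[4]], prod(spacing)),
    left_drainage = region_mask("left_drainage",
                                sort(c(idx[[1]], idx[[3]])), prod(spacing)),
    right_drainage = region_mask("right_drainage",
                                 sort(c(idx[[2]], idx[[4]])), prod(spacing)),
    aorta = region_mask("aorta", idx[[5]], prod(spacing)),
    background = region_mask("background", bg_band, prod(spacing))
  )
  structure(list(modality = "mru", data = dyn, structural = structural,
                 labels = lab, masks = masks, schedule = schedule,
                 spacing = spacing, aif = aif, truth = truth, spec = spec),
            class = "phantom_study")
}

sim_drs <- function(spec, schedule, aif, left, right, truth, pixel_mm,
                    noise) {
  a_l <- kidney_semiaxis(spec$volume_left)
  a_r <- kidney_semiaxis(spec$volume_right)
  a_max <- max(a_l, a_r)
  dim2 <- c(ceiling(2 * (a_max * 1.6 + a_max + 26) / pixel_mm / 2) * 2,
            ceiling((a_max * 6.5 + 70) / pixel_mm / 2) * 2)
  cz <- -a_max * 1.2                       # kidney centre height
  cx_l <- a_l + 22; cx_r <- -(a_r + 22)
  kid_l <- ellipse_mask2d(dim2, pixel_mm, c(cx_l, cz), c(a_l, 2 * a_l))
  kid_r <- ellipse_mask2d(dim2, pixel_mm, c(cx_r, cz), c(a_r, 2 * a_r))
  pel_l <- ellipse_mask2d(dim2, pixel_mm, c(cx_l - a_l - 6, cz - a_l),
                          c(10, 10)) & !kid_l
  pel_r <- ellipse_mask2d(dim2, pixel_mm, c(cx_r + a_r + 6, cz - a_r),
                          c(10, 10)) & !kid_r
  heart <- ellipse_mask2d(dim2, pixel_mm, c(0, a_max * 2.2 + 30), c(18, 18))
  bg_l <- c_background_mask2d(dim2, pixel_mm, c(cx_l, cz),
                              c(a_l, 2 * a_l), "left") &
    !(kid_l | kid_r | pel_l | pel_r | heart)
  bg_r <- c_background_mask2d(dim2, pixel_mm, c(cx_r, cz),
                              c(a_r, 2 * a_r), "right") &
    !(kid_l | kid_r | pel_l | pel_r | heart)

  # extensive amounts per side (counts ~ volume x intensive curve)
  amt_l <- (attr(left, "parenchyma") + attr(left, "pelvis")) *
    spec$volume_left
  amt_r <- (attr(right, "parenchyma") + attr(right, "pelvis")) *
    spec$volume_right
  s <- spec$drs_count_scale / max(amt_l, amt_r)
  pk_px <- max(s * amt_l / sum(kid_l | pel_l),
               s * amt_r / sum(kid_r | pel_r))
  bg_trace <- spec$background_level * pk_px * aif$value / max(aif$value)
  heart_trace <- 0.8 * spec$drs_count_scale * aif$value / max(aif$value) /
    sum(heart)

  n_sp <- prod(dim2); nf <- n_frames(schedule)
  flat <- numeric(n_sp * nf)
  flat <- add_trace(flat, n_sp, seq_len(n_sp), bg_trace)  # soft tissue
  flat <- add_trace(flat, n_sp, which(kid_l),
                    s * attr(left, "parenchyma") * spec$volume_left /
                      sum(kid_l))
  flat <- add_trace(flat, n_sp, which(kid_r),
                    s * attr(right, "parenchyma") * spec$volume_right /
                      sum(kid_r))
  flat <- add_trace(flat, n_sp, which(pel_l),
                    s * attr(left, "pelvis") * spec$volume_left /
                      sum(pel_l))
  flat <- add_trace(flat, n_sp, which(pel_r),
                    s * attr(right, "pelvis") * spec$volume_right /
                      sum(pel_r))
  flat <- add_trace(flat, n_sp, which(heart), heart_trace)
  if (noise) flat <- stats::rpois(length(flat), pmax(flat, 0))
  frames <- array(flat, c(dim2, nf))

  px2 <- pixel_mm^2
  masks <- list(
    left_kidney = region_mask("left_kidney", which(kid_l | pel_l), px2),
    right_kidney = region_mask("right_kidney", which(kid_r | pel_r), px2),
    heart = region_mask("heart", which(heart), px2),
    left_background = region_mask("left_background", which(bg_l), px2),
    right_background = region_mask("right_background", which(bg_r), px2)
  )
  lab <- array(0L, dim2)
  lab[kid_l | pel_l] <- 1L; lab[kid_r | pel_r] <- 2L
  lab[heart] <- 5L; lab[bg_l] <- 6L; lab[bg_r] <- 7L
  structure(list(modality = "drs", data = frames, structural = NULL,
                 labels = lab, masks = masks, schedule = schedule,
                 pixel_mm = pixel_mm, aif = aif, truth = truth,
                 spec = spec),
            class = "phantom_study")
}

#' @export
print.phantom_study <- function(x, ...) {
  cat(sprintf("<phantom_study> %s, grid %s, %d frames\n", x$modality,
              paste(utils::head(dim(x$data), -1), collapse = "x"),
              n_frames(x$schedule)))
  print(x$truth)
  invisible(x)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf(
    "<phantom_truth> SRF %.2f/%.2f, volumes %.0f/%.0f mL, patterns %s/%s\n",
    x$srf_left, x$srf_right, x$volume_left, x$volume_right,
    x$pattern_left, x$pattern_right))
  invisible(x)
}

#' Write a simulated study to disk
#'
#' Curves go to CSV (`time_s,duration_s,value`), the image series to
#' NIfTI-1, the ground truth to a JSON sidecar.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(study$masks)) {
    cv <- extract_curve(study, study$masks[[nm]])
    write_tac(cv, file.path(dir, paste0(nm, ".csv")))
  }
  pix <- if (study$modality == "mru") c(study$spacing, 1) else
    c(study$pixel_mm, study$pixel_mm, 1)
  img <- RNifti::asNifti(study$data, pixdim = pix)
  RNifti::writeNifti(img, file.path(dir, "series.nii.gz"))
  if (!is.null(study$structural))
    RNifti::writeNifti(RNifti::asNifti(study$structural,
                                       pixdim = study$spacing),
                       file.path(dir, "structural.nii.gz"))
  jsonlite::write_json(unclass(study$truth),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
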