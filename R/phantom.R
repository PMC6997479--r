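#' Phantom specification for a paired renography study
#'
#' Parameters of the digital renal phantom. The per-side uptake constants
#' (`patlak_slope_*`, per second, per unit parenchymal volume) and the
#' parenchymal volumes jointly define the ground-truth split renal function
#'
#' \deqn{SRF_L = 100 \frac{V_L K_L}{V_L K_L + V_R K_R}}
#'
#' which is recorded in the returned object and in every
#' [phantom_truth] emitted by [simulate_study()].
#'
#' @param volume_left,volume_right Parenchymal volumes, mL.
#' @param patlak_slope_left,patlak_slope_right Per-unit-volume uptake
#'   constants K, 1/s (signal units per aortic-signal-second).
#' @param blood_volume_fraction Dimensionless vascular (intercept) term
#'   V_b of the Rutland-Patlak model.
#' @param drainage_pattern_left,drainage_pattern_right One of `"normal"`,
#'   `"borderline"`, `"accumulation"`.
#' @param outflow_rate_normal Pelvic outflow rate constant for the normal
#'   pattern, 1/s.
#' @param outflow_rate_borderline Outflow rate for the borderline pattern,
#'   1/s, or `NULL` to solve numerically for the rate that holds the
#'   whole-ROI curve at a late plateau (95% of its peak).
#' @param outflow_rate_accumulation Outflow rate for the accumulation
#'   pattern; must be 0 (no drainage).
#' @param transit_time Parenchymal transit time, s: delay between filtration
#'   and arrival of tracer in the collecting system.
#' @param bolus_peak_time Time of the aortic first-pass peak, s.
#' @param bolus_alpha,bolus_beta Gamma-variate shape/scale of the aortic
#'   bolus (dimensionless / s).
#' @param recirculation_fraction Recirculation plateau as a fraction of the
#'   first-pass peak.
#' @param mru_noise_sd Additive Gaussian noise SD for the fMRU series
#'   (signal a.u.), or `NULL` for the default of 1% of the noise-free
#'   parenchymal peak signal.
#' @param drs_count_scale Expected peak kidney counts per frame for the DRS
#'   series (Poisson scale).
#' @param background_level DRS soft-tissue background, as a fraction of the
#'   peak kidney per-pixel count rate.
#' @param seed Integer RNG seed; the full study is reproducible from it.
#' @return An object of class `phantom_spec`.
#' @seealso [spec_for_srf()], [simulate_study()], [renal_curve()]
#' @export
phantom_spec <- function(volume_left = 120, volume_right = 120,
                         patlak_slope_left = 0.01,
                         patlak_slope_right = 0.01,
                         blood_volume_fraction = 0.1,
                         drainage_pattern_left = "normal",
                         drainage_pattern_right = "normal",
                         outflow_rate_normal = 0.02,
                         outflow_rate_borderline = NULL,
                         outflow_rate_accumulation = 0,
                         transit_time = 150,
                         bolus_peak_time = 40,
                         bolus_alpha = 3,
                         bolus_beta = 6,
                         recirculation_fraction = 0.05,
                         mru_noise_sd = NULL,
                         drs_count_scale = 10000,
                         background_level = 0.3,
                         seed = 1L) {
  patterns <- c("normal", "borderline", "accumulation")
  drainage_pattern_left <- match.arg(drainage_pattern_left, patterns)
  drainage_pattern_right <- match.arg(drainage_pattern_right, patterns)
  if (volume_left <= 0 || volume_right <= 0) stop("volumes must be > 0")
  if (patlak_slope_left < 0 || patlak_slope_right < 0)
    stop("uptake slopes must be >= 0")
  if (outflow_rate_normal < 0 ||
      (!is.null(outflow_rate_borderline) && outflow_rate_borderline < 0))
    stop("outflow rates must be >= 0")
  if (outflow_rate_accumulation != 0)
    stop("accumulation pattern is defined by zero outflow")
  if (blood_volume_fraction < 0) stop("blood_volume_fraction must be >= 0")
  wl <- volume_left * patlak_slope_left
  wr <- volume_right * patlak_slope_right
  if (wl + wr <= 0) stop("at least one kidney must have positive uptake")
  structure(
    list(volume_left = volume_left, volume_right = volume_right,
         patlak_slope_left = patlak_slope_left,
         patlak_slope_right = patlak_slope_right,
         blood_volume_fraction = blood_volume_fraction,
         drainage_pattern_left = drainage_pattern_left,
         drainage_pattern_right = drainage_pattern_right,
         outflow_rate_normal = outflow_rate_normal,
         outflow_rate_borderline = outflow_rate_borderline,
         outflow_rate_accumulation = outflow_rate_accumulation,
         transit_time = transit_time,
         bolus_peak_time = bolus_peak_time,
         bolus_alpha = bolus_alpha, bolus_beta = bolus_beta,
         recirculation_fraction = recirculation_fraction,
         mru_noise_sd = mru_noise_sd,
         drs_count_scale = drs_count_scale,
         background_level = background_level,
         true_srf_left = 100 * wl / (wl + wr),
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> true SRF %.1f/%.1f, volumes %.0f/%.0f mL, patterns %s/%s, seed %d\n",
    x$true_srf_left, 100 - x$true_srf_left, x$volume_left, x$volume_right,
    x$drainage_pattern_left, x$drainage_pattern_right, x$seed))
  invisible(x)
}

#' Build a phantom specification with a target split renal function
#'
#' Solves for the left uptake slope so that the ground-truth SRF equals
#' `srf_left`, given the volumes and the right slope.
#'
#' @param srf_left Target left SRF, percent, in (0, 100).
#' @param volume_left,volume_right Parenchymal volumes, mL.
#' @param patlak_slope_right Right-kidney uptake constant, 1/s.
#' @param ... Further arguments passed to [phantom_spec()].
#' @return A `phantom_spec` with `true_srf_left == srf_left`.
#' @export
spec_for_srf <- function(srf_left, volume_left = 120, volume_right = 120,
                         patlak_slope_right = 0.01, ...) {
  if (srf_left <= 0 || srf_left >= 100)
    stop("srf_left must be in (0, 100)")
  k_left <- patlak_slope_right * (volume_right / volume_left) *
    srf_left / (100 - srf_left)
  phantom_spec(volume_left = volume_left, volume_right = volume_right,
               patlak_slope_left = k_left,
               patlak_slope_right = patlak_slope_right, ...)
}

#' Ground truth of a simulated study
#'
#' Recorded before noise is added; immutable record of what the phantom
#' generator put into a study.
#'
#' @param spec The generating [phantom_spec()].
#' @return An object of class `phantom_truth` with fields `srf_left`,
#'   `srf_right`, `volume_left`, `volume_right`, `pattern_left`,
#'   `pattern_right`, `seed`.
#' @export
phantom_truth <- function(spec) {
  structure(
    list(srf_left = spec$true_srf_left,
         srf_right = 100 - spec$true_srf_left,
         volume_left = spec$volume_left, volume_right = spec$volume_right,
         pattern_left = spec$drainage_pattern_left,
         pattern_right = spec$drainage_pattern_right,
         seed = spec$seed),
    class = "phantom_truth"
  )
}

# Continuous aortic input: gamma-variate first pass, peak normalized to
# `amplitude`, plus an exponential-tail recirculation plateau at
# recirculation_fraction * peak. Vectorized over t.
aif_value <- function(t, peak_time, shape_alpha, scale_beta,
                      recirculation_fraction, amplitude = 1,
                      recirc_tau = 40) {
  t0 <- peak_time - shape_alpha * scale_beta
  u <- pmax(t - t0, 0)
  first <- ifelse(u > 0,
                  (u / (shape_alpha * scale_beta))^shape_alpha *
                    exp(shape_alpha - u / scale_beta),
                  0)
  recirc <- recirculation_fraction * (1 - exp(-u / recirc_tau))
  amplitude * (first + recirc)
}

#' Simulated aortic input function
#'
#' Gamma-variate first pass
#' \deqn{P_1(t) = A\,(t-t_0)^{\alpha} e^{-(t-t_0)/\beta}, \quad t > t_0}
#' (zero before the arrival time \eqn{t_0 = } `peak_time` \eqn{- \alpha\beta},
#' so the continuous maximum sits at `peak_time`), normalized to peak
#' `amplitude`, plus a recirculation plateau equal to
#' `recirculation_fraction` times the first-pass peak approached with an
#' exponential tail. Sampled at frame midpoints.
#'
#' @param schedule An [acquisition_schedule()].
#' @param peak_time First-pass peak time, s; must lie within the
#'   acquisition span.
#' @param shape_alpha Gamma-variate shape, `> 0`.
#' @param scale_beta Gamma-variate scale, s, `> 0`.
#' @param recirculation_fraction Plateau level as a fraction of the
#'   first-pass peak (`0` for a pure bolus).
#' @param amplitude Peak value, a.u.
#' @param recirc_tau Time constant of the recirculation rise, s.
#' @return A [tac()] labelled `"aorta"`.
#' @export
aortic_input <- function(schedule, peak_time = 40, shape_alpha = 3,
                         scale_beta = 6, recirculation_fraction = 0.1,
                         amplitude = 1, recirc_tau = 40) {
  if (shape_alpha <= 0 || scale_beta <= 0)
    stop("shape_alpha and scale_beta must be > 0")
  span <- c(schedule$start[1L],
            schedule$start[n_frames(schedule)] +
              schedule$duration[n_frames(schedule)])
  if (peak_time < span[1] || peak_time > span[2])
    stop("peak_time must lie within the acquisition span")
  mids <- schedule_midpoints(schedule)
  v <- aif_value(mids, peak_time, shape_alpha, scale_beta,
                 recirculation_fraction, amplitude, recirc_tau)
  tac_from_schedule(schedule, pmax(v, 0), label = "aorta")
}

# Two-compartment kidney: parenchyma holds filtered tracer for
# `transit_time` seconds, then hands it to the pelvis, which empties at
# rate k_out. All quantities per unit parenchymal volume:
#   parenchyma(t) = K * (cumP(t) - cumP(t - Tt)) + Vb * P(t)
#   pelvis'(t)    = K * P(t - Tt) - k_out * pelvis(t)
# Exact exponential update of the pelvis ODE between frame midpoints.
kidney_compartments <- function(K, Vb, transit_time, k_out, times, P) {
  cumP <- as.numeric(pracma::cumtrapz(c(0, times), c(0, P)))[-1L]
  if (times[1L] <= 0)
    cumP <- as.numeric(pracma::cumtrapz(times, P))
  lag_t <- times - transit_time
  cum_lag <- stats::approx(c(0, times), c(0, cumP), xout = pmax(lag_t, 0),
                           rule = 2)$y
  cum_lag[lag_t <= 0] <- 0
  paren <- K * (cumP - cum_lag) + Vb * P
  inflow <- K * stats::approx(c(0, times), c(0, P), xout = pmax(lag_t, 0),
                              rule = 2)$y
  inflow[lag_t <= 0] <- 0
  pelvis <- numeric(length(times))
  if (length(times) > 1L) {
    for (i in 2:length(times)) {
      dt <- times[i] - times[i - 1L]
      fin <- (inflow[i] + inflow[i - 1L]) / 2
      if (k_out > 0) {
        e <- exp(-k_out * dt)
        pelvis[i] <- pelvis[i - 1L] * e + fin * (1 - e) / k_out
      } else {
        pelvis[i] <- pelvis[i - 1L] + fin * dt
      }
    }
  }
  list(parenchyma = pmax(paren, 0), pelvis = pmax(pelvis, 0))
}

# Outflow rate for a side's drainage pattern. Borderline defaults to the
# rate that balances late inflow so the whole-ROI curve plateaus at 95% of
# its peak over the final minute (numeric solve; scale-invariant in K).
resolve_outflow <- function(spec, side) {
  pattern <- spec[[paste0("drainage_pattern_", side)]]
  switch(pattern,
         normal = spec$outflow_rate_normal,
         accumulation = spec$outflow_rate_accumulation,
         borderline = spec$outflow_rate_borderline)
}

solve_borderline_kout <- function(K, Vb, transit_time, times, P,
                                  target = 0.95, end_window = 60) {
  late <- times >= max(times) - end_window
  ratio <- function(k) {
    comp <- kidney_compartments(K, Vb, transit_time, k, times, P)
    total <- comp$parenchyma + comp$pelvis
    mean(total[late]) / max(total)
  }
  f <- function(logk) ratio(10^logk) - target
  lo <- -5; hi <- log10(0.5)
  flo <- f(lo); fhi <- f(hi)
  if (flo < 0) return(10^lo)    # already below plateau with no outflow
  if (fhi > 0) return(10^hi)
  10^stats::uniroot(f, c(lo, hi), tol = 1e-4)$root
}

#' Noise-free whole-kidney curve of one phantom side
#'
#' Forward model behind the phantom: irreversible (Rutland-Patlak) uptake
#' \deqn{Q(t) = K \int_0^t P(\tau)d\tau + V_b P(t)}
#' with the filtered tracer routed through the collecting system after a
#' parenchymal transit time; the pelvis empties at the pattern-specific
#' outflow rate (`0` for the accumulation pattern). Values are per unit
#' parenchymal volume; [simulate_study()] applies volume scaling for count
#' (DRS) data.
#'
#' @param spec A [phantom_spec()].
#' @param side `"left"` or `"right"`.
#' @param input Aortic input [tac()] on the same schedule.
#' @param schedule Optional [acquisition_schedule()]; defaults to the
#'   schedule implied by `input`.
#' @return A [tac()] for the whole kidney + pelvis ROI, with attributes
#'   `parenchyma`, `pelvis` (component vectors) and `k_out`.
#' @export
renal_curve <- function(spec, side = c("left", "right"), input,
                        schedule = NULL) {
  side <- match.arg(side)
  if (!inherits(input, "tac")) stop("input must be a tac")
  times <- input$time
  K <- spec[[paste0("patlak_slope_", side)]]
  Vb <- spec$blood_volume_fraction
  k_out <- resolve_outflow(spec, side)
  if (is.null(k_out))
    k_out <- solve_borderline_kout(K, Vb, spec$transit_time, times,
                                   input$value)
  comp <- kidney_compartments(K, Vb, spec$transit_time, k_out, times,
                              input$value)
  out <- tac(times, input$duration, comp$parenchyma + comp$pelvis,
             label = paste0(side, "_kidney"), modality = input$modality)
  attr(out, "parenchyma") <- comp$parenchyma
  attr(out, "pelvis") <- comp$pelvis
  attr(out, "k_out") <- k_out
  out
}
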