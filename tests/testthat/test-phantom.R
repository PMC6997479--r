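test_that("phantom_spec derives the ground-truth SRF consistently", {
  spec <- phantom_spec(volume_left = 100, volume_right = 150,
                       patlak_slope_left = 0.012, patlak_slope_right = 0.008)
  expect_equal(spec$true_srf_left,
               100 * 100 * 0.012 / (100 * 0.012 + 150 * 0.008),
               tolerance = 1e-9)
  tr <- phantom_truth(spec)
  expect_equal(tr$srf_left + tr$srf_right, 100, tolerance = 1e-9)
  sp65 <- spec_for_srf(65, volume_left = 80, volume_right = 140)
  expect_equal(sp65$true_srf_left, 65, tolerance = 1e-9)
  expect_error(phantom_spec(outflow_rate_accumulation = 0.01), "zero outflow")
  expect_error(phantom_spec(volume_left = -1), "> 0")
})

test_that("aortic input has gamma-variate shape with its peak at the stated time", {
  sch <- mru_schedule()
  # peak location of the continuous form, verified against a dense grid
  tt <- seq(0, 200, by = 0.001)
  dense <- renogram:::aif_value(tt, 40, 3, 6, 0)
  expect_equal(tt[which.max(dense)], 40, tolerance = 2e-3)
  # pure first pass decays below 1% of peak by t0 + 10 beta
  aif0 <- aortic_input(sch, recirculation_fraction = 0)
  t0 <- 40 - 3 * 6
  late <- aif0$value[aif0$time >= t0 + 10 * 6 + 15]
  expect_lt(max(late), 0.01 * max(aif0$value))
  # linearity in amplitude
  a1 <- aortic_input(sch, amplitude = 1)
  a2 <- aortic_input(sch, amplitude = 2)
  expect_equal(a2$value, 2 * a1$value, tolerance = 1e-12)
  # recirculation plateau sits at the stated fraction of the peak
  ar <- aortic_input(sch, recirculation_fraction = 0.05)
  expect_equal(ar$value[length(ar$value)], 0.05, tolerance = 0.01)
  expect_error(aortic_input(sch, shape_alpha = 0), "> 0")
  expect_error(aortic_input(sch, peak_time = 1e5), "span")
})

test_that("renal_curve reduces to closed forms in degenerate settings", {
  aif <- default_aif()
  # null kidney
  null_spec <- phantom_spec(patlak_slope_left = 0, blood_volume_fraction = 0)
  expect_equal(max(renal_curve(null_spec, "left", aif)$value), 0)
  # constant input, Vb = 0, no outflow: Q(t) = K c t within 0.5% at dt = 5 s
  sch5 <- acquisition_schedule(seq(0, by = 5, length.out = 120), rep(5, 120))
  const_p <- tac_from_schedule(sch5, rep(2, 120), label = "aorta")
  spec <- phantom_spec(patlak_slope_left = 0.004, blood_volume_fraction = 0,
                       drainage_pattern_left = "accumulation")
  q <- renal_curve(spec, "left", const_p)
  i <- 40:120  # past the initial rise-from-zero assumption
  expect_equal(q$value[i], 0.004 * 2 * q$time[i], tolerance = 0.005)
})

test_that("zero outflow conserves tracer and gives a non-decreasing curve", {
  aif <- default_aif()
  spec <- phantom_spec(drainage_pattern_left = "accumulation",
                       blood_volume_fraction = 0)
  q <- renal_curve(spec, "left", aif)
  expect_true(all(diff(q$value) >= -1e-12))
  # conservation: final value equals K * int P + Vb * P(T)
  spec_vb <- phantom_spec(drainage_pattern_left = "accumulation")
  qv <- renal_curve(spec_vb, "left", aif)
  n <- length(qv$value)
  expected <- spec_vb$patlak_slope_left * tac_cumulative(aif)[n] +
    spec_vb$blood_volume_fraction * aif$value[n]
  expect_equal(qv$value[n], expected, tolerance = 0.005)
})

test_that("normal-pattern curves peak in the interior and then decline", {
  aif <- default_aif()
  q <- renal_curve(phantom_spec(), "left", aif)
  pk <- find_peak(q)
  expect_gt(pk$index, 1)
  expect_lt(pk$index, length(q$value))
  expect_lt(q$value[length(q$value)], 0.9 * pk$value)
})

test_that("borderline outflow solve yields a late plateau", {
  aif <- default_aif()
  q <- renal_curve(phantom_spec(drainage_pattern_left = "borderline"),
                   "left", aif)
  pk <- find_peak(q)
  late <- mean(q$value[q$time >= max(q$time) - 60])
  expect_gt(late / pk$value, 0.9)
  expect_lt(late / pk$value, 1)
  expect_gt(attr(q, "k_out"), 0)
})

test_that("simulated studies are bit-identical under a fixed seed", {
  spec <- phantom_spec(seed = 17)
  expect_identical(simulate_study(spec, "mru")$data,
                   simulate_study(spec, "mru")$data)
  expect_identical(simulate_study(spec, "drs")$data,
                   simulate_study(spec, "drs")$data)
})

test_that("voxelized kidney volume matches the analytic ellipsoid", {
  # 50 mL kidney on an isotropic 2 mm grid
  a <- renogram:::kidney_semiaxis(50)
  m <- ellipsoid_mask(c(64, 64, 64), c(2, 2, 2), c(0, 0, 0), c(a, a, 2 * a))
  expect_equal(sum(m) * 8 / 1000, 50, tolerance = 0.02)
})

test_that("a symmetric noise-free phantom yields a 50/50 split downstream", {
  spec <- phantom_spec(seed = 5)
  res <- analyze_mru_study(simulate_study(spec, "mru", noise = FALSE))
  expect_equal(unname(res$srf$volumetric), c(50, 50), tolerance = 1e-9)
  expect_equal(unname(res$srf$auc), c(50, 50), tolerance = 1e-9)
})

test_that("truth is recorded before noise and matches the spec formula", {
  spec <- spec_for_srf(57.3, volume_left = 90, volume_right = 110, seed = 2)
  st <- simulate_study(spec, "drs")
  expect_equal(st$truth$srf_left, 57.3, tolerance = 1e-9)
  wl <- spec$volume_left * spec$patlak_slope_left
  wr <- spec$volume_right * spec$patlak_slope_right
  expect_equal(st$truth$srf_left, 100 * wl / (wl + wr), tolerance = 1e-9)
})
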