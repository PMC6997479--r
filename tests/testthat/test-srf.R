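test_that("auc_srf handles symmetric, single-kidney and 2:1 cases", {
  aif <- default_aif()
  q <- renal_curve(phantom_spec(), "left", aif)
  w <- uptake_window(aif)
  expect_equal(unname(auc_srf(q, q, w)), c(50, 50))
  zero <- tac(q$time, q$duration, rep(0, length(q$time)))
  expect_equal(unname(auc_srf(q, zero, w)), c(100, 0))
  expect_error(auc_srf(zero, zero, w), "undefined")
  # left = 2 x right: verify against a dense Riemann sum oracle
  q2 <- tac(q$time, q$duration, 2 * q$value)
  got <- auc_srf(q2, q, w)
  grid <- seq(w[1], w[2], length.out = 200001)
  riemann <- function(cv) mean(tac_at(cv, grid)) * diff(w)
  a_l <- riemann(q2); a_r <- riemann(q)
  expect_equal(unname(got), 100 * c(a_l, a_r) / (a_l + a_r),
               tolerance = 1e-6)
  expect_equal(unname(got), c(200 / 3, 100 / 3), tolerance = 1e-9)
})

test_that("patlak_fit recovers an exact line and known generative truth", {
  # 3-point exact line: y = 2x
  sch <- toy_schedule(3)
  renal <- toy_tac(c(2, 4, 6))
  aorta <- toy_tac(c(1, 1, 1))
  # with P = 1, x = cum(t) grows linearly; construct y = Q/P directly
  # via a synthetic renal curve equal to 2 * cumP
  cumP <- tac_cumulative(aorta)
  renal <- toy_tac(2 * cumP)
  fit <- patlak_fit(renal, aorta, c(0, 3))
  expect_equal(fit$slope_K, 2, tolerance = 1e-9)
  expect_equal(fit$intercept_V0, 0, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  # generative round trip: K = 0.004, Vb = 0.1
  aif <- default_aif()
  spec <- phantom_spec(patlak_slope_left = 0.004,
                       blood_volume_fraction = 0.1)
  q <- renal_curve(spec, "left", aif)
  f2 <- patlak_fit(q, aif, uptake_window(aif))
  expect_equal(f2$slope_K, 0.004, tolerance = 0.01)
  expect_equal(f2$intercept_V0, 0.1, tolerance = 0.05)
  # pure vascular ROI: Q = c * P -> slope 0, intercept c
  vasc <- tac(aif$time, aif$duration, 0.3 * aif$value)
  f3 <- patlak_fit(vasc, aif, uptake_window(aif))
  expect_equal(f3$slope_K, 0, tolerance = 1e-9)
  expect_equal(f3$intercept_V0, 0.3, tolerance = 1e-9)
})

test_that("patlak_fit equals a brute-force least-squares solver", {
  aif <- default_aif()
  q <- add_curve_noise(renal_curve(phantom_spec(), "left", aif), 0.02, 9)
  w <- uptake_window(aif)
  fit <- patlak_fit(q, aif, w)
  sel <- q$time >= w[1] & q$time <= w[2] & aif$value > 0
  x <- tac_cumulative(aif)[sel] / aif$value[sel]
  y <- q$value[sel] / aif$value[sel]
  # normal equations solved directly
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(fit$intercept_V0, beta[1], tolerance = 1e-9)
  expect_equal(fit$slope_K, beta[2], tolerance = 1e-9)
})

test_that("patlak_fit errors on unusable windows and drops bad frames", {
  aif <- default_aif()
  q <- renal_curve(phantom_spec(), "left", aif)
  expect_error(patlak_fit(q, aif, c(100, 60)), "window")
  dead <- tac(aif$time, aif$duration, rep(0, length(aif$time)))
  expect_error(suppressWarnings(patlak_fit(q, dead, c(60, 160))), "usable")
})

test_that("patlak_srf is ratio arithmetic with a floor at zero", {
  mk <- function(k) structure(list(slope_K = k), class = "patlak_fit")
  expect_equal(unname(patlak_srf(mk(0.01), mk(0.01))), c(50, 50))
  expect_equal(unname(patlak_srf(mk(0.03), mk(0.01))), c(75, 25))
  expect_warning(res <- patlak_srf(mk(-0.002), mk(0.01)), "floored")
  expect_equal(unname(res), c(0, 100))
  expect_error(suppressWarnings(patlak_srf(mk(0), mk(0))), "undefined")
})

test_that("SRF estimates are invariant under common positive rescaling", {
  aif <- default_aif()
  spec <- spec_for_srf(62)
  l <- add_curve_noise(renal_curve(spec, "left", aif), 0.01, 3)
  r <- add_curve_noise(renal_curve(spec, "right", aif), 0.01, 4)
  w <- uptake_window(aif)
  scale_tac <- function(cv, s) tac(cv$time, cv$duration, s * cv$value)
  expect_equal(auc_srf(scale_tac(l, 5.5), scale_tac(r, 5.5), w),
               auc_srf(l, r, w), tolerance = 1e-9)
  s1 <- patlak_srf(patlak_fit(l, aif, w), patlak_fit(r, aif, w))
  a2 <- scale_tac(aif, 2.5)
  s2 <- patlak_srf(patlak_fit(scale_tac(l, 5.5), a2, w),
                   patlak_fit(scale_tac(r, 5.5), a2, w))
  expect_equal(s1, s2, tolerance = 1e-9)
})

test_that("segment_volume recovers phantom ellipsoid volumes", {
  a <- renogram:::kidney_semiaxis(120)
  dims <- c(80, 40, 60)
  vol <- array(0, dims)
  vol[ellipsoid_mask(dims, c(2, 2, 2), c(35, 0, 0), c(a, a, 2 * a))] <- 1
  vol[ellipsoid_mask(dims, c(2, 2, 2), c(-35, 0, 0), c(a, a, 2 * a))] <- 1
  seg <- segment_volume(vol, 0.5, voxel_volume = 8)
  expect_equal(seg$n_components, 2)
  expect_equal(seg$volume_left, 120, tolerance = 0.03)
  # two equal ellipsoids segment to identical volumes
  expect_equal(seg$volume_left, seg$volume_right, tolerance = 1e-12)
  # empty frame errors; single component reports the missing side
  expect_error(segment_volume(array(0, c(4, 4, 4)), 0.5, 8), "empty")
  single <- array(0, dims)
  single[ellipsoid_mask(dims, c(2, 2, 2), c(35, 0, 0), c(a, a, 2 * a))] <- 1
  s1 <- segment_volume(single, 0.5, 8)
  expect_true(is.na(s1$volume_right))
  expect_match(s1$flags, "right side missing")
})

test_that("volumetric_srf weights per-volume indices by volume", {
  expect_equal(unname(volumetric_srf(0.01, 0.01, 100, 100)), c(50, 50))
  expect_equal(unname(volumetric_srf(0.01, 0.01, 200, 100)),
               c(200 / 3, 100 / 3), tolerance = 1e-9)
  expect_error(volumetric_srf(0.01, 0.01, -5, 100), "> 0")
  expect_error(volumetric_srf(0, 0, 100, 100), "undefined")
})

test_that("every SRF pair sums to exactly 100", {
  aif <- default_aif()
  set.seed(31)
  for (srf in c(20, 50, 80)) {
    spec <- spec_for_srf(srf)
    l <- add_curve_noise(renal_curve(spec, "left", aif), 0.02,
                         seed = srf)
    r <- add_curve_noise(renal_curve(spec, "right", aif), 0.02,
                         seed = srf + 1)
    w <- uptake_window(aif)
    expect_equal(sum(auc_srf(l, r, w)), 100, tolerance = 1e-9)
    pf <- patlak_srf(patlak_fit(l, aif, w), patlak_fit(r, aif, w))
    expect_equal(sum(pf), 100, tolerance = 1e-9)
    expect_equal(sum(volumetric_srf(0.01, 0.008, 120, 90)), 100,
                 tolerance = 1e-9)
  }
})

test_that("noise-free phantoms are recovered within half a point", {
  spec <- spec_for_srf(70, volume_left = 110, volume_right = 95, seed = 8,
                       drainage_pattern_right = "borderline")
  mru <- analyze_mru_study(simulate_study(spec, "mru", noise = FALSE))
  drs <- analyze_drs_study(simulate_study(spec, "drs", noise = FALSE))
  expect_lt(abs(mru$srf$volumetric["left"] - 70), 0.5)
  expect_lt(abs(drs$srf$patlak["left"] - 70), 0.5)
  expect_lt(abs(drs$srf$auc["left"] - 70), 0.5)
})
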