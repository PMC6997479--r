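test_that("schedules enforce frame invariants", {
  expect_error(acquisition_schedule(c(0, 4), c(5, 5)), "overlap")
  expect_error(acquisition_schedule(c(0, 5), c(5, 0)), "> 0")
  expect_error(acquisition_schedule(c(5, 0), c(1, 1)), "increasing")
  s <- mru_schedule()
  expect_equal(n_frames(s), 70)
  expect_equal(s$start[61], 300)
  expect_equal(sum(s$duration), 600)
  expect_equal(n_frames(drs_schedule()), 120)
  expect_equal(sum(drs_schedule()$duration), 1200)
})

test_that("tac validates and round-trips through CSV", {
  expect_error(tac(c(1, 2), 1, c(1, NA)), "finite")
  expect_error(tac(c(2, 1), 1, c(1, 2)), "increasing")
  cv <- toy_tac(c(1, 5, 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_tac(cv, path)
  back <- read_tac(path, label = "x")
  expect_equal(back$time, cv$time)
  expect_equal(back$value, cv$value)
})

test_that("extract_curve means mru series and sums drs series", {
  # constant field -> constant curve
  sch <- toy_schedule(3)
  arr <- array(7, c(2, 2, 2, 3))
  mk <- region_mask("left_kidney", 1:8, 8)
  cv <- extract_curve(arr, mk, schedule = sch)
  expect_equal(cv$value, rep(7, 3))
  # single-voxel mask reproduces that voxel's trace
  arr[1, 1, 1, ] <- c(1, 2, 3)
  one <- extract_curve(arr, region_mask("aorta", 1, 8), schedule = sch)
  expect_equal(one$value, c(1, 2, 3))
  # two-voxel mean, hand-computed on a 3-frame toy series
  arr[2, 1, 1, ] <- c(3, 4, 5)
  two <- extract_curve(arr, region_mask("aorta", 1:2, 8), schedule = sch)
  expect_equal(two$value, c(2, 3, 4))
  # drs sums counts
  schd <- toy_schedule(3, modality = "drs")
  sums <- extract_curve(arr, region_mask("aorta", 1:2, 8), schedule = schd)
  expect_equal(sums$value, c(4, 6, 8))
  expect_error(extract_curve(arr, region_mask("aorta", 99, 8),
                             schedule = sch), "outside")
})

test_that("background subtraction follows the size-ratio rule and clips", {
  kid <- toy_tac(c(10, 20))
  bg0 <- toy_tac(c(0, 0))
  expect_equal(background_subtract(kid, bg0)$value, kid$value)
  expect_equal(background_subtract(kid, kid, 1)$value, c(0, 0))
  bg <- toy_tac(c(2, 4))
  expect_equal(background_subtract(kid, bg, size_ratio = 2)$value, c(6, 12))
  # negative results are clipped and counted
  over <- background_subtract(toy_tac(c(1, 10)), toy_tac(c(5, 1)))
  expect_equal(over$value, c(0, 9))
  expect_equal(attr(over, "n_clipped"), 1)
  expect_error(background_subtract(kid, toy_tac(c(1, 2, 3))), "schedule")
})

test_that("extract-then-subtract is linear in the series values", {
  sch <- toy_schedule(4)
  set.seed(42)
  arr <- array(runif(2 * 2 * 1 * 4), c(2, 2, 1, 4))
  kid_m <- region_mask("left_kidney", 1:2, 1)
  bg_m <- region_mask("background", 3:4, 1)
  corr1 <- background_subtract(extract_curve(arr, kid_m, schedule = sch),
                               extract_curve(arr, bg_m, schedule = sch))
  corr3 <- background_subtract(
    extract_curve(3 * arr, kid_m, schedule = sch),
    extract_curve(3 * arr, bg_m, schedule = sch))
  expect_equal(corr3$value, 3 * corr1$value, tolerance = 1e-12)
})

test_that("resample_uniform is exact on linear data and preserves bounds", {
  ramp <- toy_tac(seq(0, 9), dt = 2)
  rs <- resample_uniform(ramp, 0.7)
  expect_equal(rs$value, (rs$time - ramp$time[1]) / 2, tolerance = 1e-12)
  expect_equal(rs$time[1], ramp$time[1])
  expect_equal(rs$time[length(rs$time)], ramp$time[length(ramp$time)])
  # idempotent at the native dt
  same <- resample_uniform(ramp, 2)
  expect_equal(same$value, ramp$value)
  # no overshoot beyond original bounds
  set.seed(1)
  wig <- toy_tac(runif(20), dt = 3)
  rs2 <- resample_uniform(wig, 0.5)
  expect_gte(min(rs2$value), min(wig$value))
  expect_lte(max(rs2$value), max(wig$value))
})

test_that("dual-rate phantom curve resampled at 5 s preserves its integral", {
  aif <- default_aif()
  rc <- renal_curve(phantom_spec(), "left", aif)
  rs <- resample_uniform(rc, 5)
  expect_equal(tac_integral(rs), tac_integral(rc), tolerance = 0.01)
})

test_that("find_peak locates maxima with earliest-tie and flat handling", {
  inc <- toy_tac(1:10)
  expect_equal(find_peak(inc, 1)$index, 10)
  tri <- toy_tac(c(1, 2, 5, 2, 1))
  expect_equal(find_peak(tri, 1)$index, 3)
  # earliest tie
  tie <- toy_tac(c(0, 3, 1, 3, 0))
  expect_equal(find_peak(tie, 1)$index, 2)
  flat <- toy_tac(rep(2, 6))
  pk <- find_peak(flat)
  expect_equal(pk$index, 1)
  expect_true("flat curve" %in% pk$flags)
  expect_error(find_peak(tri, 4), "odd")
})

test_that("find_peak is invariant under positive affine value scaling", {
  aif <- default_aif()
  noisy <- add_curve_noise(aif, 0.02, 5)
  scaled <- tac(noisy$time, noisy$duration, 3.7 * noisy$value + 11)
  expect_equal(find_peak(scaled)$index, find_peak(noisy)$index)
})

test_that("smoothed peak of a noisy bolus lands within one frame", {
  aif <- default_aif()
  true_i <- find_peak(aif)$index
  hits <- sum(vapply(1:100, function(s) {
    abs(find_peak(add_curve_noise(aif, 0.02, s), 5)$index - true_i) <= 1
  }, logical(1)))
  expect_gte(hits, 95)
})
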