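test_that("stage-I objective is the weighted squared error", {
  cfg <- tune_config()
  m0 <- structure(list(mass = cfg$anchors[1], fwhm = cfg$tfw[1],
                       intensity = 1e5), class = "peak_measurement")
  expect_equal(evaluate_tune_objective(m0, cfg, "I", 1), 0)
  m1 <- structure(list(mass = cfg$anchors[1] + 0.2, fwhm = cfg$tfw[1] + 0.1,
                       intensity = 1e5), class = "peak_measurement")
  expect_equal(evaluate_tune_objective(m1, cfg, "I", 1), 0.01 + 0.04)
  # stage II returns the intensity; the pass predicate is true at equality
  m2 <- structure(list(mass = 59, fwhm = 0.6, intensity = cfg$it),
                  class = "peak_measurement")
  expect_equal(evaluate_tune_objective(m2, cfg, "II"), cfg$it)
  expect_true(evaluate_tune_objective(m2, cfg, "II") >= cfg$it)
})

test_that("noiseless mass-axis calibration converges in a single correction", {
  truth <- test_truth()
  cfg <- tune_config()
  set.seed(21)
  st <- detuned_settings(truth)
  ma <- calibrate_mass_axis(truth, st, cfg, noise = FALSE)
  expect_true(all(ma$iterations <= 2))
  for (i in seq_along(truth$anchors)) {
    pk <- measure_peak(acquire_spectrum(truth, ma$settings, truth$anchors[i],
                                       noise = FALSE))
    expect_lt(abs(pk$mass - truth$anchors[i]), cfg$mass_axis_target)
  }
  expect_gt(ma$model$r2, 0.99)
  expect_gt(ma$model$omega, 0)
})

test_that("anchors already within the bound receive zero corrections", {
  truth <- test_truth()
  st <- true_settings(truth)
  ma <- calibrate_mass_axis(truth, st, tune_config(), noise = FALSE)
  expect_equal(ma$iterations, c(0L, 0L, 0L))
  expect_equal(ma$settings$dac, st$dac)
})

test_that("mass-axis calibration aborts with a diagnostic when no peak exists", {
  truth <- test_truth()
  st <- true_settings(truth)
  st$dac <- st$dac + truth$omega * 10  # peak pushed out of the window
  expect_error(calibrate_mass_axis(truth, st, tune_config()),
               "no peak")
})

test_that("noisy mass-axis calibration keeps every anchor within the spec bound", {
  truth <- test_truth()
  cfg <- tune_config()
  set.seed(31)
  st <- detuned_settings(truth)
  ma <- calibrate_mass_axis(truth, st, cfg)
  for (i in seq_along(truth$anchors)) {
    mm <- measure_settings(truth, ma$settings, truth$anchors[i])
    expect_lte(abs(mm$mass - truth$anchors[i]), 0.2)
  }
})

test_that("resolution calibration at the truth terminates immediately", {
  truth <- test_truth()
  st <- true_settings(truth)
  set.seed(41)
  rs <- calibrate_resolution(truth, st, tune_config())
  expect_equal(rs$iterations, 0L)
  expect_true(rs$converged)
})

test_that("noiseless resolution calibration recovers targets to within 1%", {
  truth <- test_truth()
  # strict thresholds force refinement; warm-started passes accumulate
  # progress exactly as the alternation loop does
  cfg <- tune_config(eps_i = (0.01 * c(0.6, 0.7, 0.725))^2)
  set.seed(51)
  st <- settings_at_truth(truth, offset = runif(3, -8, 8))
  for (pass in 1:4) {
    rs <- calibrate_resolution(truth, st, cfg, noise = FALSE)
    st <- rs$settings
    if (rs$converged) break
  }
  expect_true(rs$converged)
  expect_true(all(abs(rs$fwhm - cfg$tfw) / cfg$tfw <= 0.01))
})

test_that("single-anchor calibration lands inside the segment windows", {
  truth <- test_truth()
  cfg <- tune_config()
  for (anchor in c(1L, 3L)) {
    for (r in 1:2) {
      set.seed(60 + 10 * anchor + r)
      st <- settings_at_truth(truth, offset = runif(3, -8, 8))
      rs <- calibrate_resolution(truth, st, cfg, anchors = anchor)
      win <- cfg$fwhm_windows[[anchor]]
      expect_gte(rs$fwhm, win[1])
      expect_lte(rs$fwhm, win[2])
    }
  }
})

test_that("unreachable target widths fail at the cap without an exception", {
  truth <- test_truth(fwhm_floor = 1.2, fwhm_at_target = c(1.3, 1.3, 1.3))
  cfg <- tune_config(n_iter = 5, m = 8)
  set.seed(71)
  st <- settings_at_truth(truth, offset = runif(3, -8, 8))
  rs <- calibrate_resolution(truth, st, cfg, anchors = 1)
  expect_false(rs$converged)
  expect_equal(rs$iterations, 5L)
})

test_that("source optimization recovers the optimum on a noiseless instrument", {
  truth <- test_truth()
  cfg <- tune_config(it = Inf, n_iter = 30)  # unattainable threshold: run to cap
  set.seed(81)
  st <- detuned_settings(truth)
  st <- settings_at_truth(truth, source = st$source)
  sp <- optimize_source_params(truth, st, cfg, noise = FALSE)
  expect_false(sp$converged)  # threshold unattainable by design
  frac <- abs(sp$settings$source - truth$source_opt) /
    (truth$source_upper - truth$source_lower)
  expect_true(all(frac < 0.02))
})

test_that("source optimization started at the optimum stops at once", {
  truth <- test_truth()
  st <- true_settings(truth)
  set.seed(91)
  sp <- optimize_source_params(truth, st, tune_config())
  expect_equal(sp$iterations, 0L)
  expect_true(sp$converged)
  expect_gte(sp$intensity, tune_config()$it)
})

test_that("a full auto-tune from the truth passes immediately and is seed-stable", {
  truth <- test_truth()
  st <- true_settings(truth)
  a <- run_autotune(truth, st, tune_config(), seed = 7)
  expect_true(a$condition1)
  expect_true(a$condition2)
  expect_true(all(a$pass_fwhm))
  expect_true(all(a$pass_mass))
  expect_true(all(a$pass_intensity))
  expect_equal(a$outer_passes, 1L)
  b <- run_autotune(truth, st, tune_config(), seed = 7)
  expect_identical(a$fwhm, b$fwhm)
  expect_identical(a$mass_shift, b$mass_shift)
  expect_identical(a$settings, b$settings)
})

test_that("auto-tune from a detuned start meets the tuning specification", {
  truth <- test_truth()
  cfg <- tune_config()
  set.seed(101)
  st <- detuned_settings(truth)
  rep <- run_autotune(truth, st, cfg, seed = 102)
  expect_true(rep$condition1)
  expect_true(all(abs(rep$mass_shift) <= cfg$mass_tol))
  for (i in 1:3) {
    expect_gte(rep$fwhm[i], cfg$fwhm_windows[[i]][1])
    expect_lte(rep$fwhm[i], cfg$fwhm_windows[[i]][2])
  }
  expect_gte(min(rep$intensity), cfg$it)
})
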