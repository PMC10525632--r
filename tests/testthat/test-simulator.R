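test_that("control interpolation is linear with segment extrapolation", {
  m <- c(100, 200, 400)
  v <- c(10, 30, 20)
  expect_equal(interpolate_control(m, v, 200), 30)
  expect_equal(interpolate_control(m, v, 150), 20)   # midpoint mean
  expect_equal(interpolate_control(m, v, 300), 25)
  expect_equal(interpolate_control(m, v, 50), 0)     # left extrapolation
  expect_equal(interpolate_control(m, v, 500), 15)   # right extrapolation
  # collinear anchors reproduce the straight line everywhere
  line <- 50 * m + 120
  for (q in c(80, 250, 1000)) {
    expect_equal(interpolate_control(m, line, q), 50 * q + 120)
  }
  expect_error(interpolate_control(100, 10, 150), "anchors")
})

test_that("noiseless acquisition at ground truth reproduces the truth exactly", {
  truth <- test_truth()
  st <- true_settings(truth)
  for (i in seq_along(truth$anchors)) {
    pk <- measure_peak(acquire_spectrum(truth, st, truth$anchors[i],
                                        noise = FALSE))
    expect_lt(abs(pk$mass - truth$anchors[i]), truth$grid_step)
    expect_lt(abs(pk$fwhm - truth$fwhm_at_target[i]),
              0.01 * truth$fwhm_at_target[i])
    expect_equal(pk$intensity, truth$i_max, tolerance = 1e-6)
  }
})

test_that("a DAC offset of omega/2 shifts the centroid by half an m/z", {
  truth <- test_truth()
  st <- true_settings(truth)
  st$dac <- st$dac + truth$omega * 0.5
  pk <- measure_peak(acquire_spectrum(truth, st, 616.46, noise = FALSE))
  expect_lt(abs((pk$mass - 616.46) - 0.5), truth$grid_step)
})

test_that("the decoy mode caps the apex at its relative height", {
  truth <- test_truth(decoy = list(location = c(42, 75, 150, 4), height = 0.6))
  st <- true_settings(truth)
  st$source <- truth$decoy$location
  pk <- measure_peak(acquire_spectrum(truth, st, 59.05, noise = FALSE))
  expected <- truth$i_max *
    (truth$source_floor + (1 - truth$source_floor) *
       (0.6 + exp(-0.5 * sum(((truth$decoy$location - truth$source_opt) /
                                truth$source_sigma)^2))))
  expect_equal(pk$intensity, expected, tolerance = 1e-6)
  expect_lt(pk$intensity, 0.7 * truth$i_max)
})

test_that("peak metrology round-trips noiseless Gaussians", {
  truth <- test_truth()
  st <- true_settings(truth)
  # closed form: FWHM of a sigma = 0.3 Gaussian is 2*sqrt(2*log(2))*0.3
  truth2 <- test_truth(fwhm_at_target = rep(2 * sqrt(2 * log(2)) * 0.3, 3))
  pk <- measure_peak(acquire_spectrum(truth2, true_settings(truth2), 59.05,
                                      noise = FALSE))
  expect_equal(pk$fwhm, 0.7064472, tolerance = 1e-3)
  # grid of generating parameters
  for (fw in c(0.4, 0.7, 1.1)) {
    for (shift in c(-0.8, 0, 1.2)) {
      t3 <- test_truth(fwhm_at_target = rep(fw, 3))
      s3 <- true_settings(t3)
      s3$dac <- s3$dac + t3$omega * shift
      pk <- measure_peak(acquire_spectrum(t3, s3, 616.46, noise = FALSE))
      expect_lt(abs(pk$mass - (616.46 + shift)), t3$grid_step)
      expect_lt(abs(pk$fwhm - fw) / fw, 0.01)
    }
  }
})

test_that("an empty or flat spectrum raises a no-peak error", {
  spec <- structure(list(mz = seq(58, 60, 0.01),
                         intensity = rep(0, 201)), class = "spectrum")
  expect_error(measure_peak(spec), class = "ipsotune_no_peak")
  expect_error(measure_peak(structure(list(mz = numeric(0),
                                           intensity = numeric(0)),
                                      class = "spectrum")))
  # a peak outside the window leaves baseline only
  truth <- test_truth()
  st <- true_settings(truth)
  st$dac <- st$dac + truth$omega * 10  # 10 m/z off, outside the +/-3 window
  sp <- acquire_spectrum(truth, st, 59.05, noise = FALSE)
  expect_error(measure_peak(sp, floor = truth$detection_floor),
               class = "ipsotune_no_peak")
})

test_that("measured FWHM grows monotonically with the offset deviation", {
  truth <- test_truth()
  st <- true_settings(truth)
  fw <- sapply(seq(-3, 3, by = 1), function(d) {
    s2 <- st
    s2$offset[2] <- truth$offset_true[2] + d
    measure_peak(acquire_spectrum(truth, s2, 616.46, noise = FALSE))$fwhm
  })
  expect_true(all(diff(fw) > 0))
})

test_that("centroid shift is linear in the DAC deviation with slope 1/omega", {
  truth <- test_truth()
  st <- true_settings(truth)
  dacs <- seq(-80, 80, by = 20)
  shifts <- sapply(dacs, function(d) {
    s2 <- st
    s2$dac <- s2$dac + d
    measure_peak(acquire_spectrum(truth, s2, 616.46, noise = FALSE))$mass - 616.46
  })
  fit <- lm(shifts ~ dacs)
  expect_gt(summary(fit)$r.squared, 0.999)
  expect_equal(unname(coef(fit)[2]), 1 / truth$omega, tolerance = 1e-3)
})

test_that("ground truth serialises to JSON and back", {
  truth <- test_truth(decoy = list(location = c(42, 75, 150, 4), height = 0.5))
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(truth, path)
  back <- read_ground_truth(path)
  expect_equal(back$omega, truth$omega)
  expect_equal(back$anchors, truth$anchors)
  expect_equal(back$decoy$height, 0.5)
  expect_equal(back$source_sigma, truth$source_sigma)
})

test_that("averaged measurements reduce noise", {
  truth <- test_truth()
  st <- true_settings(truth)
  set.seed(4)
  one <- replicate(40, measure_settings(truth, st, 616.46, n_acq = 1)$mass)
  avg <- replicate(40, measure_settings(truth, st, 616.46, n_acq = 5)$mass)
  expect_lt(sd(avg), sd(one))
})
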