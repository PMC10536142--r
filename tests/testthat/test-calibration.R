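test_that("a single straight line is fitted exactly by every segment", {
  ad <- seq(100, 1000, length.out = 80)
  sw <- calibration_sweep(ad, 2 * ad, "loading")
  fit <- fit_piecewise(sw, n_segments = 9)
  expect_equal(fit$slopes, rep(2, 9), tolerance = 1e-8)
  expect_equal(fit$intercepts, rep(0, 9), tolerance = 1e-5)
  expect_lt(max(abs(predict(fit, ad) - 2 * ad)), 1e-6)
})

test_that("a known 4-segment generator is recovered at all sample points", {
  gen <- pl_curve(c(100, 300, 500, 700, 1000), c(0, 50, 300, 320, 600))
  ad <- seq(100, 1000, length.out = 150)
  sw <- calibration_sweep(ad, gen(ad), "loading")
  fit <- fit_piecewise(sw, n_segments = 4)
  expect_lt(max(abs(predict(fit, ad) - gen(ad))), 1e-6)
})

test_that("fitted curves are continuous at interior breakpoints", {
  gen <- pl_curve(c(0, 800, 1500, 2500, 4000), c(10, 120, 180, 420, 500))
  ad <- seq(0, 4000, length.out = 240)
  fit <- fit_piecewise(calibration_sweep(ad, gen(ad), "loading"), 6)
  eps <- 1e-7
  for (b in fit$breakpoints[-c(1, length(fit$breakpoints))]) {
    left <- predict(fit, b - eps, warn = FALSE)
    right <- predict(fit, b + eps, warn = FALSE)
    expect_lt(abs(left - right), 1e-4)
  }
})

test_that("monotone noise-free data yield a monotone fit", {
  gen <- function(ad) 500 * (ad / 4000)^2 + 30
  ad <- seq(200, 3800, length.out = 300)
  fit <- fit_piecewise(calibration_sweep(ad, gen(ad), "loading"), 9)
  grid <- seq(200, 3800, length.out = 1000)
  expect_true(all(diff(predict(fit, grid)) >= -1e-9))
})

test_that("too few points or a degenerate AD range is rejected", {
  expect_error(fit_piecewise(calibration_sweep(1:10, 1:10, "loading"), 9),
               class = "rehabband_input_error")
  sw <- calibration_sweep(rep(500, 40), rep(100, 40), "loading")
  expect_error(fit_piecewise(sw, 9), class = "rehabband_input_error")
})

test_that("hysteresis pair fitting validates sweep directions", {
  ad <- seq(100, 1000, length.out = 60)
  up <- calibration_sweep(ad, ad, "loading")
  down <- calibration_sweep(rev(ad), rev(ad), "unloading")
  expect_error(fit_hysteresis_pair(down, down, 4),
               class = "rehabband_input_error")
  expect_error(fit_hysteresis_pair(up, up, 4),
               class = "rehabband_input_error")
  expect_s3_class(fit_hysteresis_pair(up, down, 4), "hysteresis_calibration")
})

test_that("prediction averages the two branches; zero hysteresis reproduces either", {
  gen <- pl_curve(c(100, 400, 700, 1000), c(0, 100, 350, 500))
  ad <- seq(100, 1000, length.out = 120)
  up <- calibration_sweep(ad, gen(ad), "loading")
  down_same <- calibration_sweep(rev(ad), gen(rev(ad)), "unloading")
  cal0 <- fit_hysteresis_pair(up, down_same, 3)
  expect_lt(max(abs(predict(cal0, ad) - predict(cal0$up, ad))), 1e-8)

  # constant 40 gf offset loop: averaged prediction = loading generator + 20
  down_off <- calibration_sweep(rev(ad), gen(rev(ad)) + 40, "unloading")
  cal <- fit_hysteresis_pair(up, down_off, 3)
  expect_lt(max(abs(predict(cal, ad) - (gen(ad) + 20))), 1e-4)
  expect_lt(max(abs(predict(cal$down, ad) - predict(cal$up, ad) - 40)), 1e-4)
})

test_that("extrapolation outside the calibrated range continues the terminal segments", {
  ad <- seq(100, 1000, length.out = 60)
  fit <- fit_piecewise(calibration_sweep(ad, 2 * ad + 5, "loading"), 2)
  expect_warning(p <- predict(fit, c(50, 1100)), "extrapolating")
  expect_equal(p, 2 * c(50, 1100) + 5, tolerance = 1e-6)
})

test_that("calibration error report follows f_error = f_predict - f_true", {
  rep1 <- calibration_error(310, 300)
  expect_equal(rep1$f_error, 10)
  expect_equal(rep1$percent_error, 100 * 10 / 300, tolerance = 1e-12)
  expect_equal(calibration_error(300, 300)$f_error, 0)
  dead <- calibration_error(280, 0)
  expect_equal(dead$f_error, 280)
  expect_true(is.na(dead$percent_error))
  expect_true(dead$undefined)
  expect_error(calibration_error(10, -1), class = "rehabband_input_error")
})

test_that("calibration JSON round-trips and sweeps round-trip through CSV", {
  gen <- pl_curve(c(100, 500, 1000), c(0, 200, 450))
  sweeps <- generate_calibration_sweep(gen, function(a) gen(a) + 30,
                                       ad_range = c(100, 1000),
                                       n_points = 120, seed = 2)
  cal <- fit_hysteresis_pair(sweeps$up, sweeps$down, 2)
  tf <- tempfile(fileext = ".json")
  write_calibration(cal, tf)
  cal2 <- read_calibration(tf)
  ad <- seq(150, 950, length.out = 37)
  expect_equal(predict(cal2, ad), predict(cal, ad), tolerance = 1e-12)

  cf <- tempfile(fileext = ".csv")
  write_sweeps(sweeps, cf)
  back <- read_sweeps(cf)
  expect_equal(back$loading$ad, sweeps$up$ad)
  expect_equal(back$unloading$force, sweeps$down$force)
})
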