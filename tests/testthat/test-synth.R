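test_that("templates start and end at rest, stay distinct, and pass the gate", {
  tpl <- action_templates()
  cfg <- detection_config()
  expect_length(tpl, 4)
  for (m in tpl) {
    expect_equal(dim(m), c(3, 30))
    expect_equal(m[, 1], rep(0, 3), tolerance = 1e-12)
    expect_equal(m[, 30], rep(0, 3), tolerance = 1e-12)
    prefix_range <- apply(m[, 1:10], 1, function(v) max(v) - min(v))
    expect_gt(max(prefix_range), cfg$t1)
    expect_true(is_action(1 + m, cfg))
  }
  for (pr in combn(4, 2, simplify = FALSE))
    expect_gt(max(abs(tpl[[pr[1]]] - tpl[[pr[2]]])), 0.1)
})

test_that("the noise- and jitter-free limit reproduces the scaled template", {
  prof <- subject_profile(baseline = c(1000, 1250, 950), amp_jitter = 0,
                          time_jitter = 0, noise_sd = 0)
  s1 <- generate_action_sample(2, prof, seed = 1)
  s2 <- generate_action_sample(2, prof, seed = 999)
  expect_identical(unclass(s1), unclass(s2))
  expected <- round((1 + action_templates()[[2]]) * prof$baseline)
  expect_equal(unclass(s1), expected, ignore_attr = TRUE)
})

test_that("generated samples keep head and tail near the resting level", {
  prof <- subject_profile(baseline = c(1000, 1200, 900))
  for (s in 1:40) {
    raw <- suppressWarnings(generate_action_sample(((s - 1) %% 4) + 1, prof,
                                                   seed = s))
    u <- normalize_sample(raw, prof$baseline)
    expect_lt(min(abs(u[, 1] - u[, 30])), 0.03)
  }
})

test_that("dataset dimensions, references, and seeding behave as specified", {
  ds <- generate_dataset(5, 50, seed = 77)
  expect_length(ds$samples, 1000)
  expect_equal(nrow(ds$references), 5)
  expect_equal(sort(unique(ds$labels)), 1:4)
  expect_equal(as.integer(table(ds$labels)), rep(250L, 4))

  ds2 <- generate_dataset(5, 50, seed = 77)
  expect_identical(ds, ds2)
  ds3 <- generate_dataset(5, 50, seed = 78)
  expect_false(identical(ds$samples[[1]], ds3$samples[[1]]))

  # normalized resting samples have per-channel mean 1 by construction
  for (s in 1:5) {
    ref <- rehabband:::lookup_reference(ds$references, s, 1)
    expect_true(all(ref > 0))
  }
  expect_error(generate_dataset(0, 5), class = "rehabband_input_error")
})

test_that("every dataset sample passes the gate when normalized by its reference", {
  ds <- generate_dataset(2, 10, seed = 13)
  cfg <- detection_config()
  for (i in seq_along(ds$samples)) {
    ref <- rehabband:::lookup_reference(ds$references, ds$subject[i], ds$round[i])
    expect_true(is_action(normalize_sample(ds$samples[[i]], ref), cfg))
  }
})

test_that("sessions concatenate rest, actions, switches with exact ground truth", {
  prof <- subject_profile(baseline = c(1100, 1000, 1300))
  sch <- list(list(type = "rest", n = 50),
              list(type = "action", label = 3),
              list(type = "rest", n = 20),
              list(type = "switch", delta = c(0.1, 0.1, 0.1), n = 40),
              list(type = "action", label = 1),
              list(type = "rest", n = 10))
  ses <- generate_session(prof, sch, seed = 2)
  expect_equal(nrow(ses$stream), 50 + 30 + 20 + 40 + 30 + 10)
  expect_equal(ses$truth$onset, c(51L, 141L))
  expect_equal(ses$truth$label, c(3L, 1L))
  ses2 <- generate_session(prof, sch, seed = 2)
  expect_identical(ses, ses2)
  expect_error(generate_session(prof, list()), class = "rehabband_input_error")
})

test_that("calibration sweeps reproduce their generating curves when fitted", {
  gen_up <- pl_curve(c(200, 1200, 2600, 3800), c(30, 120, 380, 500))
  gen_dn <- function(ad) gen_up(ad) + 40
  sweeps <- generate_calibration_sweep(gen_up, gen_dn, n_points = 200, seed = 4)
  expect_s3_class(sweeps$up, "calibration_sweep")
  expect_identical(sweeps$up$direction, "loading")
  cal <- fit_hysteresis_pair(sweeps$up, sweeps$down, 3)
  ad <- seq(250, 3750, length.out = 60)
  expect_lt(max(abs(predict(cal$up, ad) - gen_up(ad))), 1e-4)
  expect_lt(max(abs(predict(cal, ad) - (gen_up(ad) + 20))), 1e-4)
  sw2 <- generate_calibration_sweep(gen_up, gen_dn, n_points = 200, seed = 4)
  expect_identical(sweeps, sw2)
})
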