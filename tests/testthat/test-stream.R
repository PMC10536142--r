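test_that("reference initialization averages the leading stream samples", {
  stream <- data.frame(t = 1:40, ch1 = 1000, ch2 = 1100, ch3 = 900)
  expect_equal(as.numeric(initialize_reference(stream)), c(1000, 1100, 900))
  expect_error(initialize_reference(stream[1:20, ]),
               class = "rehabband_input_error")

  prof <- subject_profile(baseline = c(1200, 900, 1500))
  ses <- generate_session(prof, list(list(type = "rest", n = 30)), seed = 3)
  ref <- initialize_reference(ses$stream)
  # within 3 standard errors of the true baseline (sigma = 0.01 ratio units)
  expect_true(all(abs(as.numeric(ref) / prof$baseline - 1) <
                    3 * 0.01 / sqrt(30) + 0.01))
})

test_that("pipeline training, prediction and gating fit together", {
  pipe <- fixture_pipeline()
  expect_s3_class(pipe, "rehab_pipeline")
  expect_lt(pipe$training$error_rate, 0.02)

  rest <- matrix(1, 3, 30)
  expect_true(is.na(predict_window(pipe, rest)))

  ds <- fixture_test()
  i <- which(ds$labels == 3)[1]
  ref <- rehabband:::lookup_reference(ds$references, ds$subject[i], ds$round[i])
  w <- normalize_sample(ds$samples[[i]], ref)
  out <- predict_window(pipe, w)
  expect_identical(as.integer(out), 3L)
  expect_identical(sum(attr(out, "tallies")), 6L)
  expect_identical(as.integer(predict_window(pipe, w)), as.integer(out))
})

test_that("held-out subjects are recognized almost perfectly", {
  pipe <- fixture_pipeline()
  ds <- fixture_test()
  pred <- predict(pipe, rehabband:::dataset_features(ds))
  met <- compute_metrics(confusion_matrix(ds$labels, pred))
  expect_gte(met$macro$f1, 95)
})

test_that("the streaming detector recovers scheduled actions and ignores rest and ramps", {
  pipe <- fixture_pipeline()
  prof <- subject_profile(baseline = c(1000, 1200, 900))

  set.seed(41)
  labs <- sample(1:4, 20, replace = TRUE)
  ses <- generate_session(prof, action_schedule(labs), seed = 42)
  ev <- run_detector(pipe, ses$stream)
  expect_equal(nrow(ev), 20)
  expect_equal(ev$label, labs)
  expect_true(all(rowSums(ev[, c("v1", "v2", "v3", "v4")]) == 6))

  rest_only <- generate_session(prof, list(list(type = "rest", n = 500)),
                                seed = 5)
  expect_equal(nrow(run_detector(pipe, rest_only$stream)), 0)

  # a posture switch spread over 240 samples keeps the 10-sample drift an
  # order of magnitude below the peak threshold even with sensor noise;
  # steeper ramps are intentionally indistinguishable from an action onset
  ramps <- generate_session(prof, list(
    list(type = "rest", n = 80),
    list(type = "switch", delta = c(0.15, 0.18, 0.2), n = 240),
    list(type = "rest", n = 80),
    list(type = "switch", delta = -c(0.15, 0.18, 0.2), n = 240),
    list(type = "rest", n = 80)), seed = 6)
  expect_equal(nrow(run_detector(pipe, ramps$stream)), 0)
})

test_that("streaming detection equals the materialized-window oracle", {
  pipe <- fixture_pipeline()
  prof <- subject_profile(baseline = c(1300, 1000, 1150))
  set.seed(17)
  labs <- sample(1:4, 5, replace = TRUE)
  ses <- generate_session(prof, action_schedule(labs), seed = 18)
  ev <- run_detector(pipe, ses$stream)
  oracle <- batch_detect_oracle(pipe, ses$stream)
  expect_equal(ev$sample_index, oracle$sample_index)
  expect_equal(ev$label, oracle$label)
  # determinism of the streaming pass
  expect_identical(run_detector(pipe, ses$stream), ev)
})

test_that("events honor the refractory contract", {
  pipe <- fixture_pipeline()
  prof <- subject_profile(baseline = c(1000, 1100, 1200))
  set.seed(23)
  ses <- generate_session(prof, action_schedule(sample(1:4, 8, replace = TRUE),
                                                rest_n = 35), seed = 24)
  ev <- run_detector(pipe, ses$stream)
  if (nrow(ev) > 1)
    expect_true(all(diff(ev$sample_index) > pipe$config$refractory))
})

test_that("malformed stream rows are skipped with a warning, or fatal in strict mode", {
  pipe <- fixture_pipeline()
  prof <- subject_profile(baseline = c(1000, 1100, 1200))
  ses <- generate_session(prof, action_schedule(2L), seed = 31)
  stream <- ses$stream
  stream$ch2[c(5, 50)] <- NA
  expect_warning(ev <- run_detector(pipe, stream), "malformed")
  expect_s3_class(ev, "detection_events")
  expect_error(suppressWarnings(run_detector(pipe, stream, strict = TRUE)),
               class = "rehabband_input_error")
})

test_that("bundles round-trip with bitwise-identical predictions", {
  pipe <- fixture_pipeline()
  tf <- tempfile(fileext = ".json")
  save_bundle(pipe, tf, reference = c(1000, 1200, 900))
  back <- load_bundle(tf)
  expect_equal(attr(back, "reference"), c(1000, 1200, 900))

  ds <- fixture_test()
  x <- rehabband:::dataset_features(ds)[1:25, ]
  expect_identical(predict(back, x), predict(pipe, x))
  expect_identical(encode(back$autoencoder, x[1, ]),
                   encode(pipe$autoencoder, x[1, ]))
})

test_that("corrupted or inconsistent bundles fail to load with diagnostics", {
  tf <- tempfile(fileext = ".json")
  writeLines("{ not json", tf)
  expect_error(load_bundle(tf), class = "rehabband_input_error")

  pipe <- fixture_pipeline()
  tf2 <- tempfile(fileext = ".json")
  save_bundle(pipe, tf2)
  l <- jsonlite::read_json(tf2, simplifyVector = TRUE)
  l$ensemble$code_dim <- 7
  jsonlite::write_json(l, tf2, auto_unbox = TRUE, digits = NA)
  expect_error(load_bundle(tf2), class = "rehabband_input_error")
})
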