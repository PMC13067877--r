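test_that("LHS sampling is stratified, bounded and seeded", {
  m <- lhs_sample(5, seed = 3)
  expect_equal(dim(m), c(5, 9))
  expect_true(all(m >= 0.2 & m <= 3.0))
  # per dimension: exactly one sample in each of 5 equal-width strata
  for (j in seq_len(ncol(m))) {
    strata <- floor((m[, j] - 0.2) / (3.0 - 0.2) * 5)
    expect_setequal(strata, 0:4)
  }
  expect_identical(lhs_sample(5, seed = 3), m)
  expect_false(identical(lhs_sample(5, seed = 4), m))
  expect_error(lhs_sample(0), "n_models")
  expect_error(lhs_sample(5, low_frac = 2, high_frac = 1), "low_frac")
})

test_that("calibration filter applies inclusive bands per biomarker", {
  r <- calibration_ranges()
  f <- list(rmp = -90, apa = 110, apd20 = 150, apd50 = 200, apd90 = 300)
  expect_true(calibration_filter(f, r))
  f$rmp <- -80
  expect_false(calibration_filter(f, r))
  f$rmp <- -90; f$apd90 <- 331 # boundary is inclusive
  expect_true(calibration_filter(f, r))
  f$apd90 <- NULL
  expect_error(calibration_filter(f, r), "apd90")
})

test_that("stability filter reproduces its canonical exclusions", {
  clean <- make_ap_trace(synthetic_ap_spec())
  expect_true(stability_filter(clean)$accepted)
  alt <- make_ap_trace(synthetic_ap_spec(
    apd90_per_beat = c(300, 240, 300), n_beats = 3))
  expect_equal(stability_filter(alt)$reason, "alternans")
  drift <- make_ap_trace(synthetic_ap_spec(diastolic_drift = 0.5))
  expect_equal(stability_filter(drift)$reason, "self_stimulation")
  ead <- make_ap_trace(synthetic_ap_spec(
    ead = list(amplitude = 10, onset_frac = 0.4)))
  expect_equal(stability_filter(ead)$reason, "repolarization_abnormality")
  short <- make_ap_trace(synthetic_ap_spec(n_beats = 2))
  expect_error(stability_filter(short), "3 recorded beats")
})

test_that("population statuses are exhaustive and filters idempotent", {
  pop <- cached("pop10", build_population(
    10, pacing_protocol(n_beats = 20), seed = 2, keep_states = TRUE))
  expect_length(pop$status, 10)
  allowed <- c("accepted", "excluded:no_capture", "excluded:alternans",
               "excluded:repolarization_abnormality",
               "excluded:self_stimulation", "excluded:calibration")
  expect_true(all(pop$status %in% allowed))
  expect_equal(nrow(pop$features), 10)
  # no model is both accepted and excluded; statuses partition the draw
  expect_equal(sum(pop$status == "accepted") +
                 sum(startsWith(pop$status, "excluded:")), 10)
  # re-applying the calibration filter to accepted models changes nothing
  acc <- accepted_models(pop)
  if (length(acc$idx)) {
    again <- vapply(acc$idx, function(i)
      calibration_filter(as.list(pop$features[i, ]), pop$ranges),
      logical(1))
    expect_true(all(again))
  }
})

test_that("population persists to CSV with JSON metadata", {
  pop <- cached("pop10", build_population(
    10, pacing_protocol(n_beats = 20), seed = 2, keep_states = TRUE))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_population(pop, tmp)
  df <- read.csv(tmp)
  expect_equal(nrow(df), 10)
  expect_true(all(c("INa", "IKr", "status", "apd90") %in% names(df)))
  meta <- jsonlite::read_json(paste0(tmp, ".json"), simplifyVector = TRUE)
  expect_equal(meta$seed, 2)
  expect_equal(meta$ranges$apd90, c(250, 331))
})

test_that("filter logic accepts models inside explicitly supplied bands", {
  # mechanics check with bands centred on this model's own features: the
  # calibration filter must accept it, and the pipeline must then carry it
  g <- conductance_scaling(IKr = 0.8)
  tr <- run_single_cell(g, quick_protocol(20), drift_guard = FALSE)
  f <- extract_features(tr)
  r <- calibration_ranges(rmp = f$rmp + c(-5, 5), apa = f$apa + c(-5, 5),
                          apd20 = f$apd20 + c(-20, 20),
                          apd50 = f$apd50 + c(-20, 20),
                          apd90 = f$apd90 + c(-20, 20))
  expect_true(calibration_filter(f, r))
})
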