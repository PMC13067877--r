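test_that("features of constructed waveforms match analytic truth", {
  sp <- synthetic_ap_spec(apd30 = 200, apd90 = 300, dt = 0.1)
  tr <- make_ap_trace(sp)
  f <- extract_features(tr)
  expect_lt(abs(f$apd90 - 300), 2 * tr$dt)
  expect_lt(abs(f$apd30 - 200), 2 * tr$dt)
  expect_lt(abs(f$apd20 - tr$truth$apd20), 2 * tr$dt)
  expect_lt(abs(f$apd50 - tr$truth$apd50), 2 * tr$dt)
  expect_equal(f$rmp, -85)
  expect_equal(f$apa, 125, tolerance = 1e-6)
  expect_equal(f$triangulation, f$apd90 - f$apd30)
})

test_that("square pulse has equal APDs and exact amplitude", {
  dt <- 0.1; bcl <- 800
  one <- rep(-85, bcl / dt)
  one[seq_len(200 / dt)] <- 25
  tr <- manual_trace(rep(one, 3), dt, bcl)
  f <- extract_features(tr)
  expect_equal(f$apa, 110)
  for (nm in c("apd20", "apd50", "apd90"))
    expect_lt(abs(f[[nm]] - 200), 2 * dt)
})

test_that("features are invariant to a uniform time shift", {
  tr <- make_ap_trace(synthetic_ap_spec())
  tr2 <- tr; tr2$t <- tr$t + 1234.5
  f1 <- extract_features(tr); f2 <- extract_features(tr2)
  for (nm in c("rmp", "apa", "apd30", "apd90"))
    expect_equal(f2[[nm]], f1[[nm]])
})

test_that("a late EAD prolongs APD90 relative to the clean twin", {
  clean <- make_ap_trace(synthetic_ap_spec())
  ead <- make_ap_trace(synthetic_ap_spec(
    ead = list(amplitude = 10, onset_frac = 0.88, width = 30)))
  expect_gt(extract_features(ead)$apd90, extract_features(clean)$apd90)
})

test_that("non-captured beats yield undefined durations, not errors", {
  tr <- manual_trace(rep(-85, 3 * 8000), 0.1, 800)
  f <- extract_features(tr)
  expect_false(f$capture)
  expect_true(is.na(f$apd90))
})

test_that("B2 and B6 honor their strict thresholds", {
  th <- detector_thresholds()
  mk <- function(apd90s) make_ap_trace(synthetic_ap_spec(
    apd90_per_beat = apd90s, n_beats = length(apd90s)))
  # 370 vs baseline 300 = 23.3% > 20% -> flags
  ev <- detect_events(mk(c(370, 370, 370)), 300, th)
  expect_true(ev[["b2"]])
  # exactly 20% is a strict boundary: anchor the baseline to the measured
  # drugged APD90 so discretization cannot tip the ratio
  tr360 <- mk(c(360, 360, 360))
  a360 <- extract_features(tr360)$apd90
  expect_false(detect_events(tr360, a360 / 1.2, th)[["b2"]])
  expect_true(detect_events(tr360, a360 / 1.21, th)[["b2"]])
  # alternans rule on the last three beats
  ev <- detect_events(mk(c(300, 300, 320)), 300, th)
  expect_true(ev[["b6"]])
  ev <- detect_events(mk(c(300, 300, 312)), 300, th)
  expect_false(ev[["b6"]])
})

test_that("peak and RMP detectors flag on the stated bounds", {
  th <- detector_thresholds()
  ev <- detect_events(make_ap_trace(synthetic_ap_spec(peak_override = 55)),
                      300, th)
  expect_true(ev[["b5"]]); expect_false(ev[["b4"]])
  ev <- detect_events(make_ap_trace(synthetic_ap_spec(peak_override = -5)),
                      300, th)
  expect_true(ev[["b4"]]); expect_false(ev[["b5"]])
  ev <- detect_events(make_ap_trace(synthetic_ap_spec(rmp = -45, apa = 85)),
                      300, th)
  expect_true(ev[["b3"]])
})

test_that("each detector responds to its dedicated perturbation only", {
  th <- detector_thresholds(b8_triangulation = 180)
  base <- synthetic_ap_spec()
  perturb <- list(
    b1 = synthetic_ap_spec(diastolic_drift = 0.05),
    b2 = synthetic_ap_spec(apd30 = 260, apd90 = 390),
    b3 = synthetic_ap_spec(rmp = -45, apa = 85),
    b4 = synthetic_ap_spec(peak_override = -5),
    b5 = synthetic_ap_spec(peak_override = 55),
    b6 = synthetic_ap_spec(alternans_delta = 0.08),
    b7 = synthetic_ap_spec(ead = list(amplitude = 10, onset_frac = 0.4)),
    b8 = synthetic_ap_spec(apd30 = 40, apd90 = 300))
  clean <- detect_events(make_ap_trace(base), 300, th)
  expect_false(any(clean))
  sens <- vapply(names(perturb), function(b)
    as.logical(detect_events(make_ap_trace(perturb[[b]]), 300, th)),
    logical(8))
  rownames(sens) <- paste0("b", 1:8)
  # one-hot: the sensitivity matrix is the identity
  expect_equal(unname(sens), diag(8) == 1)
})

test_that("alternans deltas straddle the 5% rule", {
  th <- detector_thresholds()
  ev <- detect_events(make_ap_trace(synthetic_ap_spec(
    alternans_delta = 0.08)), 300, th)
  expect_true(ev[["b6"]])
  ev <- detect_events(make_ap_trace(synthetic_ap_spec(
    alternans_delta = 0.04)), 300, th)
  expect_false(ev[["b6"]])
})

test_that("qnet integrates net current with the stated conventions", {
  nmc <- c("ICaL", "INaL", "IKr", "IKs", "IK1", "Ito")
  t <- seq(0, 100, by = 0.1)
  cur0 <- matrix(0, length(t), 6, dimnames = list(NULL, nmc))
  expect_equal(qnet(t, cur0), 0)
  cur1 <- cur0; cur1[, "IKr"] <- 1
  expect_equal(qnet(t, cur1), 0.1, tolerance = 1e-12)
  expect_error(qnet(t[-1], cur1), "mismatch")
  expect_error(qnet(t, cur1[, 1:3]), "columns")
})

test_that("drug-free qnet exceeds qnet under hERG block", {
  amp <- baseline_amp()
  st <- ord_limit_cycle_state(protocol = pacing_protocol(
    n_beats = 30, stim_amplitude = amp))
  p1 <- pacing_protocol(n_beats = 3, n_recorded_beats = 3,
                        stim_amplitude = amp)
  free <- run_single_cell(protocol = p1, initial = st,
                          record_currents = TRUE, drift_guard = FALSE)
  g <- apply_drug(conductance_scaling(), "dofetilide", 3)
  blocked <- run_single_cell(g, p1, initial = st, record_currents = TRUE,
                             drift_guard = FALSE)
  expect_gt(qnet_trace(free), qnet_trace(blocked))
})
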