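test_that("derivative interface enforces the membrane equation algebra", {
  y <- ord_initial_state()
  d0 <- ord_derivatives(y, istim = 0)$derivatives[["v"]]
  d5 <- ord_derivatives(y, istim = 5)$derivatives[["v"]]
  # Cm = 1: the stimulus adds to dV/dt exactly
  expect_equal(d5 - d0, 5, tolerance = 1e-12)
  ybad <- y; ybad["cai"] <- NaN
  expect_error(ord_derivatives(ybad), "cai")
  yneg <- y; yneg["ki"] <- -1
  expect_error(ord_derivatives(yneg), "ki")
})

test_that("the paced limit cycle has a quiescent diastole", {
  st <- ord_limit_cycle_state(protocol = quick_protocol(40))
  d <- ord_derivatives(st, istim = 0)
  expect_lt(abs(d$derivatives[["v"]]), 1e-3)
  # gates in [0, 1], concentrations positive
  gates <- st[10:38]
  expect_true(all(gates >= 0 & gates <= 1))
})

test_that("runs are deterministic and zero stimulus gives no capture", {
  p <- quick_protocol(6)
  t1 <- run_single_cell(protocol = p, drift_guard = FALSE)
  t2 <- run_single_cell(protocol = p, drift_guard = FALSE)
  expect_identical(t1$v, t2$v)
  expect_identical(t1$final_state, t2$final_state)
  p0 <- pacing_protocol(n_beats = 4, stim_amplitude = 0)
  tr <- run_single_cell(protocol = p0, drift_guard = FALSE)
  expect_false(tr$capture)
  expect_lt(diff(range(tr$v)), 5) # stays near diastole
})

test_that("baseline paced features lie in the physiological bands", {
  tr <- baseline_trace()
  f <- extract_features(tr)
  expect_gt(f$rmp, -95); expect_lt(f$rmp, -85)
  expect_gt(f$apd90, 250); expect_lt(f$apd90, 331)
  expect_gt(f$apd50, 181); expect_lt(f$apd50, 251)
  expect_gt(f$dvdt_max_upstroke, 100)
  expect_lt(tr$apd90_drift, 2) # steady-state drift guard over last beats
})

test_that("IKr block monotonically prolongs repolarization", {
  # acute block: a single drugged beat from the baseline limit cycle
  # (sustained full block develops 2:1 responses whose last-beat APD is
  # not comparable)
  st <- ord_limit_cycle_state(protocol = quick_protocol(40))
  apd <- function(s) {
    tr <- run_single_cell(conductance_scaling(IKr = s),
                          pacing_protocol(n_beats = 3, n_recorded_beats = 3,
                                          stim_amplitude = baseline_amp()),
                          initial = st, drift_guard = FALSE)
    a <- extract_features(tr, beat = 1)$apd90
    if (is.na(a)) Inf else a # failure to repolarize = unbounded APD
  }
  a1 <- apd(1); a05 <- apd(0.5); a0 <- apd(0)
  expect_gt(a05, a1)
  expect_gt(a0, a05)
})

test_that("stimulus threshold bisection honors its contract", {
  p <- pacing_protocol()
  amp <- baseline_amp()
  expect_true(is.finite(amp) && amp > 0)
  cap <- function(a) arscore:::ord_peak_cpp(
    as.numeric(ord_initial_state()), rep(1, 9), a, p$stim_duration, p$dt,
    60) > 0
  expect_true(cap(amp))
  expect_false(cap(0.99 * amp / 2))
  # reduced excitability raises the threshold
  amp_low_na <- find_stimulus_amplitude(conductance_scaling(INa = 0.2), p)
  expect_gte(amp_low_na, amp)
  expect_error(find_stimulus_amplitude(conductance_scaling(INa = 0),
                                       p, upper = 5), "upper")
})

test_that("trace export writes data plus metadata sidecar", {
  tr <- baseline_trace()
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_ap_trace(tr, tmp)
  df <- read.csv(tmp)
  expect_named(df, c("time", "voltage"))
  expect_equal(nrow(df), length(tr$t))
  meta <- jsonlite::read_json(paste0(tmp, ".json"))
  expect_equal(meta$bcl, 800)
  expect_true(meta$capture)
})
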