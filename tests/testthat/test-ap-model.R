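test_that("default parameters carry the canine endocardial tuning and are validated", {
  p <- apParameters()
  v <- parValues(p)
  expect_equal(v[["tau_fi"]], 0.10)
  expect_equal(v[["tau_si"]], 2.9013)
  expect_equal(v[["u_u"]], 1.56)
  expect_equal(v[["D_par"]], 0.010)
  expect_equal(v[["D_perp"]], 0.003)
  expect_true(all(v[grepl("^tau_", names(v))] > 0))
  expect_error(apParameters(tau_si = -1), "positive")
  expect_error(apParameters(D_par = 0.001), "D_par >= D_perp")
  expect_error(apParameters(bogus = 1), "unknown parameter")
  ## serialization round trip, both formats
  for (ext in c(".json", ".yaml")) {
    f <- tempfile(fileext = ext)
    writeParameters(apParameters(tau_si = 3.1), f)
    expect_equal(parValues(readParameters(f))[["tau_si"]], 3.1)
    unlink(f)
  }
})

test_that("transmembrane currents match hand evaluation of the model equations", {
  p <- apParameters()
  ## resting cancellation: all Heavisides off and u - u_o = 0
  expect_equal(unname(evaluateCurrents(c(0, 1, 1, 0), p)), c(0, 0, 0))
  ## fast inward at u = 0.5, v = 1: -(0.5 - 0.3)(1.56 - 0.5)(1)/0.10
  J <- evaluateCurrents(c(0.5, 1, 1, 0.5), p)
  expect_equal(J[["J_fi"]], -(0.5 - 0.3) * (1.56 - 0.5) * 1 / 0.10)
  expect_equal(J[["J_fi"]], -2.12)
  ## slow inward: -(w s)/tau_si
  expect_equal(J[["J_si"]], -(1 * 0.5) / 2.9013)
  ## slow outward: 1/tau_so(0.5) with the tanh form
  tauSo <- 40 + (1.2 - 40) * (1 + tanh(2 * (0.5 - 0.65))) / 2
  expect_equal(J[["J_so"]], 1 / tauSo)
  ## below theta_w the ohmic branch applies (tau_o2 since u >= theta_o)
  J2 <- evaluateCurrents(c(0.1, 1, 1, 0.1), p)
  expect_equal(J2[["J_so"]], (0.1 - 0) / 6)
  expect_equal(J2[["J_si"]], 0)
  expect_error(evaluateCurrents(c(NaN, 1, 1, 0), p), "non-finite")
})

test_that("gating rate functions follow the stated branches and tanh limits", {
  p <- apParameters()
  r <- evaluateRateFunctions(c(0, 0.5), p)
  expect_equal(r$tau_v_minus, c(55, 40))
  expect_equal(r$v_inf, c(1, 0))
  expect_equal(r$w_inf, c(1, 0.78))
  expect_equal(r$tau_s, c(2.7342, 2))
  expect_equal(r$tau_o, c(470, 6))
  ## tanh saturation limits of the slow-outward time constant
  rl <- evaluateRateFunctions(c(-100, 100), p)
  expect_equal(rl$tau_so, c(40, 1.2), tolerance = 1e-9)
  ## w_inf linear branch below theta_o
  r3 <- evaluateRateFunctions(0.003, p)
  expect_equal(r3$w_inf, 1 - 0.003 / 0.0273)
  ## Theta(0) = 1: at exactly theta_v_minus the upper branch applies
  r4 <- evaluateRateFunctions(0.2, p)
  expect_equal(r4$tau_v_minus, 40)
  expect_equal(r4$v_inf, 0)
})

test_that("the resting state is a machine-precision fixed point", {
  p <- apParameters()
  r <- restingState(p)
  expect_equal(r[["s"]], (1 + tanh(2.0994 * (0 - 0.9087))) / 2)
  after <- stepCell(r, dt = 0.01, params = p, nSteps = 200L)
  expect_lt(max(abs(after - r)), 1e-12)
  ## continuity: a vanishing step leaves any state nearly unchanged
  st <- c(u = 0.4, v = 0.7, w = 0.8, s = 0.3)
  expect_lt(max(abs(stepCell(st, dt = 1e-9, params = p) - st)), 1e-8)
  expect_error(stepCell(st, dt = 0), "positive")
})

test_that("a suprathreshold stimulus elicits a full action potential", {
  p <- apParameters()
  seqr <- runCellPacing(p, cycleLength = 600, nBeats = 2, dt = 0.02)
  tr <- attr(seqr, "trace")
  dtT <- attr(seqr, "dtTrace")
  ## upstroke beyond the fast-inward threshold within a few ms
  expect_gt(max(tr[seq_len(round(10 / dtT))]), 0.3)
  ## repolarized below 0.1 within 500 ms
  expect_lt(tr[round(500 / dtT)], 0.1)
  expect_length(apd(seqr), 2)
  expect_true(all(apd(seqr) > 100 & apd(seqr) < 350))
})

test_that("gates stay within [0, 1] during fast pacing", {
  p <- apParameters()
  res <- cardialt:::cpp_integrate_cell(
    restingState(p), cardialt:::.parVector(p), 0.02, 125000,
    (0:9) * 250, 2, 0.6, 10L, 1.0)
  tol <- 1e-6
  for (g in c("v", "w", "s")) {
    expect_gt(min(res[[g]]), -tol)
    expect_lt(max(res[[g]]), 1 + tol)
  }
})

test_that("pacing yields no alternans at slow rate and 2:2 alternans on pacing down", {
  p <- apParameters()
  slow <- runCellPacing(p, cycleLength = 1000, nBeats = 10, dt = 0.02)
  a <- apd(slow)
  expect_true(slow@captured)
  expect_lt(abs(a[10] - a[9]), 2)
  scan <- restitutionScan(p, cycleLengths = c(400, 320, 280, 240),
                          nBeats = 10, dt = 0.02)
  expect_true(any(abs(scan$delta_apd) >= 2, na.rm = TRUE))
  ## steady-state APD non-decreasing with cycle length in the 1:1 regime
  ok <- scan$captured & abs(scan$delta_apd) < 2
  expect_true(all(diff(rev(scan$apd_last[ok])) >= -0.5))
  ## n_beats bound
  two <- runCellPacing(p, cycleLength = 400, nBeats = 2, dt = 0.02)
  expect_lte(length(apd(two)), 2)
})

test_that("APD is insensitive to time-step refinement", {
  p <- apParameters()
  a1 <- apd(runCellPacing(p, cycleLength = 500, nBeats = 3, dt = 0.02))[3]
  a2 <- apd(runCellPacing(p, cycleLength = 500, nBeats = 3, dt = 0.002))[3]
  expect_lt(abs(a1 - a2) / a2, 0.01)
})

test_that("voltage rescaling is the affine map to millivolts", {
  expect_equal(rescaleVoltage(0), -84)
  expect_equal(rescaleVoltage(1), 1.7)
  expect_equal(rescaleVoltage(0.5), -41.15)
})

test_that("APD sequences export beat, APD, DI and cycle length columns", {
  p <- apParameters()
  s <- runCellPacing(p, cycleLength = 500, nBeats = 3, dt = 0.02)
  f <- tempfile(fileext = ".csv")
  writeAPDSequence(s, f)
  df <- read.csv(f)
  expect_named(df, c("beat_index", "apd_ms", "di_ms", "cycle_length_ms"))
  expect_equal(nrow(df), 3)
  ## DI + APD spans one cycle
  expect_equal(df$apd_ms[1] + df$di_ms[1], 500, tolerance = 2)
  unlink(f)
})
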