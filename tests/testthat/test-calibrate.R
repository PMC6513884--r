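test_that("EAAT decay constant follows tau = target / J0", {
  expect_equal(calibrate_eaat_tau(0.06, 3e-3), 0.05)
  expect_equal(calibrate_eaat_tau(0.06, 0), 0)
  # doubling J0 halves tau
  expect_equal(calibrate_eaat_tau(0.12, 3e-3), calibrate_eaat_tau(0.06, 3e-3) / 2)
  expect_error(calibrate_eaat_tau(0), "J0")
  expect_error(calibrate_eaat_tau(0.06, -1), "target_uptake")
})

test_that("calibration zeroes every resting transmembrane flux", {
  p <- calibrated_params()
  res <- resting_flux_residuals(p)
  expect_equal(nrow(res), 5)
  expect_true(all(abs(res$residual) < 1e-12))
  # uncalibrated parameters are far from equilibrium
  res0 <- resting_flux_residuals(psc_params())
  expect_gt(max(abs(res0$residual)), 1e-6)
})

test_that("calibration preserves the printed pump rate and channel ratios", {
  p <- calibrated_params()
  ref <- psc_params()
  expect_identical(p$astrocyte$PNKA_max, ref$astrocyte$PNKA_max)
  expect_identical(p$neuron$g_NaBNeu, ref$neuron$g_NaBNeu)
  # Kir / background ratio preserved by the common scale
  expect_equal(p$astrocyte$g_Kir / p$astrocyte$g_K,
               ref$astrocyte$g_Kir / ref$astrocyte$g_K)
  expect_lt(p$astrocyte$g_Kir, ref$astrocyte$g_Kir)
  # resting Ca2+ is the NCX equilibrium, within rounding of the table 100 nM
  expect_equal(p$astrocyte$Ca_PsC0, 1e-7, tolerance = 2e-3)
})

test_that("impossible balances raise calibration errors naming the residual", {
  # the published absolute-frame E_KNeu makes the resting voltage-gated K+
  # efflux exceed any positive-conductance balance
  p <- psc_params(E_KNeu = -0.12)
  expect_error(calibrate_background_conductances(p),
               "negative conductance")
})

test_that("stimulus calibration entrains the target rates", {
  p <- calibrated_params()
  expect_equal(calibrate_stimulus(p, 0)$amplitude, 0)
  cal <- calibrate_stimulus(p, 10)
  expect_gt(cal$amplitude, 0)
  expect_equal(cal$measured_rate, 10, tolerance = 0.05)
  expect_error(calibrate_stimulus(psc_params(), 10), "calibrate the parameter")
})

test_that("low rates are unreachable with constant current (type II neurone)", {
  p <- calibrated_params()
  err <- tryCatch(calibrate_stimulus(p, 10, type = "constant"),
                  error = function(e) conditionMessage(e))
  expect_match(err, "unreachable|bisection failed")
  expect_match(err, "Hz")
})
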