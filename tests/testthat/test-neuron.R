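test_that("HH rate constants match the classic values and handle singular points", {
  r <- hh_rates(0)
  # alpha_n(0) = 0.01 * 10 / (e - 1) per ms
  expect_equal(r[["alpha_n"]] * 1e-3, 0.1 / (exp(1) - 1), tolerance = 1e-10)
  expect_equal(r[["alpha_n"]] * 1e-3, 0.0582, tolerance = 1e-3)
  # removable singularities at +10 mV (alpha_n) and +25 mV (alpha_m)
  expect_equal(hh_rates(10e-3)[["alpha_n"]], 0.1 * 1e3, tolerance = 1e-5)
  expect_equal(hh_rates(25e-3)[["alpha_m"]], 1 * 1e3, tolerance = 1e-5)
  # limits continuous: approach from both sides
  for (v in c(9.999e-3, 10.001e-3)) {
    expect_equal(hh_rates(v)[["alpha_n"]], 100, tolerance = 1e-3)
  }
  expect_error(hh_rates(Inf), "finite")
})

test_that("steady-state gates are fixed points of the gate kinetics", {
  g <- hh_steady_gates(0)
  r <- hh_rates(0)
  for (nm in c("m", "h", "n")) {
    a <- r[[paste0("alpha_", nm)]]
    b <- r[[paste0("beta_", nm)]]
    expect_equal(a * (1 - g[[nm]]) - b * g[[nm]], 0, tolerance = 1e-12)
  }
  expect_true(all(g >= 0 & g <= 1))
})

test_that("voltage-gated sodium current has the right zeros and resting sign", {
  p <- calibrated_params()
  s <- baseline_state(p)
  # zero driving force
  s2 <- s; s2[["V_Neu"]] <- p$neuron$E_NaNeu
  expect_equal(neuron_sodium_current(s2, p), 0)
  # closed gate
  s3 <- s; s3[["m"]] <- 0
  expect_equal(neuron_sodium_current(s3, p), 0)
  # at rest: inward (negative under the efflux-positive convention)
  expect_lt(neuron_sodium_current(s, p), 0)
  # strict-as-printed mode drops the h gate and passes more current
  p2 <- p; p2$options$include_h_gate <- FALSE
  expect_gt(abs(neuron_sodium_current(s, p2)),
            abs(neuron_sodium_current(s, p)))
})

test_that("neuronal background currents are Nernst-driven and linear", {
  p <- calibrated_params()
  s <- baseline_state(p)
  # K+ baseline reversal is about -85.9 mV
  E_K <- nernst_potential(s[["K_PsECS"]], p$neuron$K_Syn)
  expect_equal(E_K, -85.9e-3, tolerance = 1e-3)
  s2 <- s; s2[["V_Neu"]] <- E_K
  expect_equal(neuron_background_current("K", s2, p), 0, tolerance = 1e-20)
  # doubling the synapse area doubles the current
  p2 <- p; p2$geometry$SA_Syn <- 2 * p$geometry$SA_Syn
  expect_equal(neuron_background_current("Na", s, p2),
               2 * neuron_background_current("Na", s, p))
})

test_that("neuronal NKA has Hill occupancies and exact 3:2 stoichiometry", {
  p <- calibrated_params()
  s <- baseline_state(p)
  nka <- neuron_nka_flux(s, p)
  occ_na <- (0.015 / 0.025)^3
  occ_k <- (0.004 / 0.0055)^2
  expect_equal(occ_na, 0.216)
  expect_equal(occ_k, 0.529, tolerance = 1e-3)
  expect_equal(nka$P, p$neuron$PNKA_maxNeu * occ_na * occ_k)
  expect_equal(nka$I_Na / nka$I_K, -3 / 2, tolerance = 1e-12)
  # no external K+: pump stalls
  s0 <- s; s0[["K_PsECS"]] <- 1e-300
  expect_equal(neuron_nka_flux(s0, p)$P, 0, tolerance = 1e-200)
})

test_that("neuron_step holds the calibrated rest and keeps gates in [0, 1]", {
  p <- calibrated_params()
  s <- baseline_state(p)
  expect_identical(neuron_step(s, 0, 0, p), s)  # dt = 0
  # 100 ms unstimulated: V stays within 0.1 mV of rest
  st <- s
  for (i in 1:10000) st <- neuron_step(st, 0, 1e-5, p)
  expect_lt(abs(st[["V_Neu"]]), 1e-4)
  # strong stimulus: gates stay clamped in [0, 1]
  st <- s
  for (i in 1:5000) {
    st <- neuron_step(st, 50, 1e-5, p)
    expect_true(all(st[c("m", "h", "n")] >= 0 & st[c("m", "h", "n")] <= 1))
  }
})

test_that("detect_spikes counts upward crossings with a refractory guard", {
  t <- seq(0, 1, by = 1e-4)
  expect_identical(detect_spikes(t, rep(0, length(t))), numeric(0))
  expect_identical(detect_spikes(numeric(0), numeric(0)), numeric(0))
  # 10 Hz sinusoid crossing +50 mV: 10 events
  v <- 0.08 * sin(2 * pi * 10 * t)
  expect_length(detect_spikes(t, v), 10)
  # two crossings 1 ms apart collapse to one event
  v2 <- rep(0, length(t))
  v2[c(100, 110)] <- 0.1
  expect_length(detect_spikes(t, v2), 1)
  # 3 ms apart: two events
  v3 <- rep(0, length(t))
  v3[c(100, 130)] <- 0.1
  expect_length(detect_spikes(t, v3), 2)
})
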