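full_currents <- function(state, params) {
  acur <- astrocyte_currents(state, params)
  ncur <- neuron_currents(state, params)
  c(as.list(acur),
    list(I_KNeu_tot = unname(ncur[["I_KNeu"]] + ncur[["I_KBNeu"]] +
                               ncur[["I_KNKANeu"]]),
         I_NaNeu_tot = unname(ncur[["I_NaNeu"]] + ncur[["I_NaBNeu"]] +
                                ncur[["I_NaNKANeu"]])))
}

test_that("concentration_rhs implements the five compartment balances", {
  p <- calibrated_params()
  s <- baseline_state(p)
  zero <- as.list(stats::setNames(rep(0, 16), names(full_currents(s, p))))
  expect_equal(unname(concentration_rhs(s, zero, p)), rep(0, 5))
  # a lone NCX Ca2+ current: d[Ca]_PsC = -I / (2 F Vol_PsC)
  cur <- zero; cur$I_CaNCX <- 1e-15
  d <- concentration_rhs(s, cur, p)
  expect_equal(d[["Ca_PsC"]], -1e-15 / (2 * 96485 * p$geometry$Vol_PS))
  expect_equal(d[["K_PsC"]], 0)
  # a pure astrocyte K+ membrane current conserves moles between PsC and PsECS
  cur <- zero; cur$I_Kir <- 3e-15
  d <- concentration_rhs(s, cur, p)
  expect_equal(p$geometry$Vol_PsECS * d[["K_PsECS"]],
               -p$geometry$Vol_PS * d[["K_PsC"]])
  expect_error(concentration_rhs(s, zero[-1], p), "missing currents")
})

test_that("euler_step leaves the state unchanged at dt = 0 and at equilibrium", {
  p <- calibrated_params()
  s <- baseline_state(p)
  expect_identical(euler_step(s, 0, p), s)
  s1 <- euler_step(s, 1e-5, p)
  concs <- c("K_PsC", "Na_PsC", "Ca_PsC", "K_PsECS", "Na_PsECS")
  expect_equal(s1[concs], s[concs], tolerance = 1e-12)
  expect_lt(abs(s1[["V_Neu"]]), 1e-15)
})

test_that("the compiled engine agrees with the pure-R reference stepper", {
  p <- calibrated_params()
  p <- short_protocol(p, t_settle = 0, t_stim = 0.003, t_post = 0,
                      type = "constant", amplitude = 0.4, record_stride = 1L)
  sim <- run_protocol(p, calibrate_amplitude = FALSE)
  # replicate in R, detecting spikes exactly as the engine does
  s <- baseline_state(p)
  thr <- p$neuron$spike_threshold
  last_spike <- -Inf
  n_steps <- 300
  for (i in seq_len(n_steps)) {
    t <- (i - 1) * 1e-5
    v_next <- neuron_step(s, 0.4, 1e-5, p)[["V_Neu"]]
    spike <- v_next >= thr && s[["V_Neu"]] < thr && (t - last_spike) >= 2e-3
    if (spike) last_spike <- t
    s <- euler_step(s, 1e-5, p, stimulus = 0.4, spike_now = spike)
  }
  final <- sim$final_state
  for (nm in c("V_Neu", "m", "h", "n", "J_NaEAAT", "K_PsC", "Na_PsC",
               "Ca_PsC", "K_PsECS", "Na_PsECS")) {
    expect_equal(unname(final[[nm]]), unname(s[[nm]]), tolerance = 1e-10,
                 label = paste("engine", nm))
  }
})

test_that("recorded engine currents match their R-level evaluations", {
  p <- calibrated_params()
  p <- short_protocol(p, t_settle = 0.1, t_stim = 1, t_post = 0.2,
                      type = "fixture",
                      spike_times = c(0.05, 0.15, 0.4), record_stride = 50L)
  sim <- run_protocol(p)
  idx <- seq(10, nrow(sim$data), by = 37)
  for (i in idx) {
    row <- sim$data[i, ]
    s <- unlist(row[c("V_Neu", "m", "h", "n", "J_NaEAAT", "K_PsC", "Na_PsC",
                      "Ca_PsC", "K_PsECS", "Na_PsECS")])
    acur <- astrocyte_currents(s, p)
    for (nm in names(acur)) {
      expect_equal(row[[nm]], acur[[nm]], tolerance = 1e-12,
                   label = paste0("t=", row$time, " ", nm))
    }
  }
})

test_that("a single glutamate event raises cradle Na+ with the peak after the spike", {
  p <- calibrated_params()
  p <- short_protocol(p, t_settle = 0.2, t_stim = 1.3, t_post = 0,
                      type = "fixture", spike_times = 0.1,
                      record_stride = 10L)
  sim <- run_protocol(p)
  d <- sim$data
  spike_t <- 0.3  # absolute time of the event
  expect_equal(sim$spike_times, spike_t, tolerance = 1e-9)
  peak_i <- which.max(d$Na_PsC)
  expect_gt(d$time[peak_i], spike_t)
  expect_gt(max(d$Na_PsC), d$Na_PsC[1])
  # and it relaxes afterwards
  expect_lt(d$Na_PsC[nrow(d)], max(d$Na_PsC))
  # J jumps to J0 at the event and decays
  expect_equal(max(d$J_NaEAAT), p$astrocyte$J0, tolerance = 5e-3)
  expect_lt(d$J_NaEAAT[nrow(d)], 1e-8)
})

test_that("identical configurations give bit-identical results", {
  p <- calibrated_params()
  p <- short_protocol(p, t_settle = 0.2, t_stim = 1, t_post = 0.2,
                      type = "pulse", rate = 20, amplitude = 0.5)
  sim1 <- run_protocol(p, calibrate_amplitude = FALSE)
  sim2 <- run_protocol(p, calibrate_amplitude = FALSE)
  expect_identical(sim1$data, sim2$data)
  expect_identical(sim1$spike_times, sim2$spike_times)
  expect_identical(sim1$meta$config_hash, sim2$meta$config_hash)
})

test_that("run_protocol refuses uncalibrated parameters and empty protocols", {
  expect_error(run_protocol(psc_params()), "not calibrated")
  p <- calibrated_params()
  p <- short_protocol(p, t_settle = 0, t_stim = 0, t_post = 0)
  expect_error(run_protocol(p), "zero total duration")
})

test_that("integration errors name the offending state variable", {
  p <- calibrated_params()
  p$astrocyte$tau_EAAT <- 1e-300   # forces a non-finite EAAT flux
  p <- short_protocol(p, t_settle = 0, t_stim = 0.01, t_post = 0,
                      type = "fixture", spike_times = 1e-4)
  expect_error(run_protocol(p), "non-finite state variable")
})
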