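test_that("EAAT flux decays exponentially and events stack additively", {
  p <- calibrated_params()
  J0 <- p$astrocyte$J0
  tau <- p$astrocyte$tau_EAAT
  # an event at rest jumps the flux to J0 = 0.06 M/s
  expect_equal(eaat_update(0, 1e-9, TRUE, p), J0, tolerance = 1e-7)
  # a second event stacks on the first
  expect_equal(eaat_update(J0, 1e-9, TRUE, p), 2 * J0, tolerance = 1e-7)
  # decay over exactly tau: J0 -> J0/e (Euler at dt = tau/1e4)
  J <- J0
  dt <- tau / 1e4
  for (i in 1:1e4) J <- eaat_update(J, dt, FALSE, p)
  expect_equal(J, J0 / exp(1), tolerance = 1e-4)
  expect_error(eaat_update(-1, 1e-5, FALSE, p), ">= 0")
  expect_error(eaat_update(0, 0, FALSE, p), "dt must be > 0")
})

test_that("one EAAT impulse integrates to the 3 mM uptake target", {
  p <- calibrated_params()
  # discrete forward-Euler integral of one impulse equals J0 * tau exactly
  J <- p$astrocyte$J0
  dt <- 1e-5
  total <- 0
  for (i in 1:200000) {  # 2 s >> tau = 50 ms
    total <- total + J * dt
    J <- J - dt * J / p$astrocyte$tau_EAAT
  }
  expect_equal(total, 3e-3, tolerance = 1e-6)
  expect_equal(p$astrocyte$J0 * p$astrocyte$tau_EAAT, 3e-3)
})

test_that("EAAT currents respect the 3 Na+ : 1 K+ stoichiometry exactly", {
  p <- calibrated_params()
  expect_identical(unname(eaat_currents(0, p)), c(0, 0))
  for (J in c(1e-4, 0.06, 0.3)) {
    cur <- eaat_currents(J, p)
    expect_identical(cur[["I_KEAAT"]], -cur[["I_NaEAAT"]] / 3)
    expect_lt(cur[["I_NaEAAT"]], 0)  # Na+ into the cradle
  }
  # magnitude: |I_NaEAAT| = J0 F Vol_PsECS at peak flux
  cur <- eaat_currents(p$astrocyte$J0, p)
  expect_equal(abs(cur[["I_NaEAAT"]]),
               p$astrocyte$J0 * 96485 * p$geometry$Vol_PsECS)
})

test_that("NCX currents match a brute-force transcription on random states", {
  p <- calibrated_params()
  a <- p$astrocyte
  set.seed(7)
  for (i in 1:1000) {
    s <- baseline_state(p)
    s[["Na_PsC"]] <- stats::runif(1, 1e-3, 0.15)
    s[["Na_PsECS"]] <- stats::runif(1, 0.01, 0.2)
    s[["Ca_PsC"]] <- stats::runif(1, 1e-9, 1e-4)
    got <- ncx_currents(s, p)
    # independent re-evaluation of the exponential-ratio rate law
    V <- a$V_A; RTF <- rtf310
    expected <- a$I_bar_NCX *
      ((s[["Na_PsC"]] / s[["Na_PsECS"]])^3 * exp(a$gamma * V / RTF) -
         (s[["Ca_PsC"]] / a$Ca_PsECS) * exp((a$gamma - 1) * V / RTF)) *
      p$geometry$SA_PS
    expect_equal(got[["I_NaNCX"]], expected, tolerance = 1e-12)
    expect_identical(got[["I_CaNCX"]], -2 * got[["I_NaNCX"]] / 3)
  }
})

test_that("the calibrated baseline sits at the NCX equilibrium", {
  p <- calibrated_params()
  s <- baseline_state(p)
  density <- ncx_currents(s, p)[["I_NaNCX"]] / p$geometry$SA_PS
  expect_lt(abs(density), 1e-5)
  # with the published (rounded) 100 nM the residual is a fraction of a uA/m^2
  p2 <- p; p2$astrocyte$Ca_PsC0 <- 1e-7
  density2 <- ncx_currents(baseline_state(p2), p2)[["I_NaNCX"]] /
    p$geometry$SA_PS
  expect_lt(abs(density2), 1e-6)
  expect_gt(abs(density2), 1e-8)
})

test_that("raising cradle Na+ from 15 to 18 mM flips the NCX into reverse mode", {
  p <- calibrated_params()
  s <- baseline_state(p)
  s[["Na_PsC"]] <- 0.018
  expect_gt(ncx_currents(s, p)[["I_NaNCX"]], 0)   # reverse: Na+ out, Ca2+ in
  expect_lt(ncx_currents(s, p)[["I_CaNCX"]], 0)
  # and lowering it goes forward
  s[["Na_PsC"]] <- 0.012
  expect_lt(ncx_currents(s, p)[["I_NaNCX"]], 0)
})

test_that("the NCX zero-crossing coincides with V_A = E_NCX", {
  p <- calibrated_params()
  cur_at <- function(na) {
    s <- baseline_state(p)
    s[["Na_PsC"]] <- na
    ncx_currents(s, p)[["I_NaNCX"]]
  }
  root <- uniroot(cur_at, c(5e-3, 40e-3), tol = 1e-12)$root
  E_Na <- nernst_potential(p$astrocyte$Na_PsECS0, root)
  E_Ca <- nernst_potential(p$astrocyte$Ca_PsECS, p$astrocyte$Ca_PsC0,
                           valence = 2)
  E_NCX <- ncx_equilibrium_potential(E_Na, E_Ca)
  expect_lt(abs(E_NCX - p$astrocyte$V_A), 0.5e-3)
})

test_that("astrocytic NKA mirrors the neuronal pump with cradle Na+", {
  p <- calibrated_params()
  s <- baseline_state(p)
  nka <- astro_nka_currents(s, p)
  expect_equal(nka$P, p$astrocyte$PNKA_max * 0.216 * (0.004 / 0.0055)^2)
  expect_equal(nka$I_Na / nka$I_K, -3 / 2, tolerance = 1e-12)
  s0 <- s; s0[["K_PsECS"]] <- 1e-300
  expect_equal(astro_nka_currents(s0, p)$P, 0, tolerance = 1e-200)
})

test_that("Kir carries a small efflux at rest and reverses when PsECS K+ rises", {
  p <- calibrated_params()
  s <- baseline_state(p)
  expect_gt(kir_current(s, p), 0)   # V_A above E_K: efflux
  s2 <- s; s2[["K_PsECS"]] <- 0.008
  expect_lt(kir_current(s2, p), 0)  # E_K above V_A: uptake
  # zero driving force
  s3 <- s
  s3[["K_PsC"]] <- s[["K_PsECS"]] / exp(p$astrocyte$V_A / rtf310)
  expect_equal(kir_current(s3, p), 0, tolerance = 1e-25)
  expect_error(kir_current(replace(s, "K_PsECS", -1), p), "> 0")
})

test_that("background currents are passive: zero at E_i, linear in g", {
  p <- calibrated_params()
  s <- baseline_state(p)
  # Na+ background is an influx pathway at baseline
  expect_lt(astro_background_current("Na", s, p), 0)
  p2 <- p; p2$astrocyte$g_Na <- 2 * p$astrocyte$g_Na
  expect_equal(astro_background_current("Na", s, p2),
               2 * astro_background_current("Na", s, p))
})

test_that("ECS leak follows the PsECS-GECS gradient and scales with area", {
  p <- calibrated_params()
  s <- baseline_state(p)
  expect_equal(ecs_leak_current("K", s, p), 0)   # at baseline: no gradient
  expect_equal(ecs_leak_current("Na", s, p), 0)
  s2 <- s; s2[["K_PsECS"]] <- 0.008
  expect_gt(ecs_leak_current("K", s2, p), 0)     # K+ leaks toward the GECS
  p2 <- p; p2$geometry$SA_PsECS_GECS <- 2 * p$geometry$SA_PsECS_GECS
  expect_equal(ecs_leak_current("K", s2, p2), 2 * ecs_leak_current("K", s2, p))
})
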