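test_that("soma-to-cradle reversal potential is Nernst-like and valence-free", {
  p <- calibrated_params()
  expect_equal(process_reversal_potential(1e-7, 1e-7, params = p), 0)
  # Ca2+ risen to 200 nM against a 100 nM soma
  expect_equal(process_reversal_potential(100e-9, 200e-9, params = p),
               rtf310 * log(0.5))
  expect_equal(process_reversal_potential(100e-9, 200e-9, params = p),
               -18.5e-3, tolerance = 1e-2)
  # strictly decreasing in the cradle concentration
  vr <- vapply(seq(50e-9, 500e-9, length.out = 20), function(cc) {
    process_reversal_potential(100e-9, cc, params = p)
  }, numeric(1))
  expect_true(all(diff(vr) < 0))
  # valence-aware option halves the Ca2+ potential
  p2 <- p; p2$options$nernst_valence <- TRUE
  expect_equal(process_reversal_potential(100e-9, 200e-9, valence = 2,
                                          params = p2),
               rtf310 * log(0.5) / 2)
})

test_that("Poole-Frenkel current vanishes without driving force and is odd in it", {
  p <- calibrated_params()
  expect_identical(poole_frenkel_current("K", 0, p), 0)
  for (vr in c(1e-3, 5e-3, 20e-3)) {
    up <- poole_frenkel_current("Na", -vr, p)  # dV = -Vr > 0: toward soma
    dn <- poole_frenkel_current("Na", vr, p)
    expect_gt(up, 0)
    expect_equal(dn, -up)  # odd symmetry: exponential even, prefactor odd
  }
})

test_that("the zero-lowering Boltzmann factor is about exp(-10) at 310 K", {
  p <- calibrated_params()
  # phi_w * Q / (k_B T) with phi_w = 0.267 eV
  exponent <- p$astrocyte$phi_w * p$constants$Q /
    (p$constants$k_B * p$constants$T)
  expect_equal(exponent, 10, tolerance = 1e-3)
  # at a vanishing driving force the barrier lowering is negligible and the
  # current approaches K * (dV/l) * exp(-10) * CSA_P
  vr <- -1e-9
  got <- poole_frenkel_current("K", vr, p)
  naive <- p$astrocyte$K_K * (-vr / p$geometry$l_P) * exp(-exponent) *
    p$geometry$CSA_P
  expect_equal(got / naive, 1, tolerance = 1e-2)
})

test_that("Poole-Frenkel current grows with |dV| and shrinks with the well depth", {
  p <- calibrated_params()
  vr <- -seq(1e-3, 50e-3, length.out = 25)  # physiological driving range
  cur <- vapply(vr, function(v) poole_frenkel_current("Ca", v, p), numeric(1))
  expect_true(all(diff(cur) > 0))
  deeper <- p; deeper$astrocyte$phi_w <- p$astrocyte$phi_w * 1.2
  for (v in c(-5e-3, -20e-3)) {
    expect_lt(poole_frenkel_current("K", v, deeper),
              poole_frenkel_current("K", v, p))
  }
})

test_that("process efflux is orders of magnitude below transmembrane currents", {
  p <- calibrated_params()
  s <- baseline_state(p)
  # a stimulated-like state: elevated cradle concentrations
  s[["K_PsC"]] <- 0.13; s[["Na_PsC"]] <- 0.022; s[["Ca_PsC"]] <- 5e-7
  cur <- astrocyte_currents(s, p)
  for (ion in c("K", "Na")) {
    pf <- abs(cur[[paste0("I_", ion, "PF")]])
    mem <- abs(cur[[paste0("I_", ion, "NKA")]])
    expect_lt(pf, 1e-3 * mem)
  }
})
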