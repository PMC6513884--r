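test_that("nernst_potential matches hand-computed values at 310 K", {
  # equal concentrations: zero driving force
  expect_identical(nernst_potential(0.1, 0.1), 0)
  # K+: 4 mM out / 100 mM in
  expect_equal(nernst_potential(0.004, 0.1), rtf310 * log(0.04))
  expect_equal(nernst_potential(0.004, 0.1), -0.0859, tolerance = 1e-3)
  # Na+: 135 mM out / 15 mM in
  expect_equal(nernst_potential(0.135, 0.015), 0.0587, tolerance = 1e-3)
  # valence divides the potential
  expect_equal(nernst_potential(1.5e-3, 1e-7, valence = 2),
               nernst_potential(1.5e-3, 1e-7) / 2)
  expect_error(nernst_potential(0, 0.1), "must be finite and > 0")
  expect_error(nernst_potential(0.1, -1), "must be finite and > 0")
})

test_that("nernst_potential is antisymmetric under swapping the two sides", {
  set.seed(42)
  for (i in 1:50) {
    a <- stats::runif(1, 1e-9, 1)
    b <- stats::runif(1, 1e-9, 1)
    z <- sample(1:2, 1)
    expect_equal(nernst_potential(a, b, z), -nernst_potential(b, a, z))
  }
})

test_that("NCX equilibrium potential follows (n E_Na - 2 E_Ca)/(n - 2)", {
  expect_identical(ncx_equilibrium_potential(0, 0), 0)
  expect_equal(ncx_equilibrium_potential(58.7e-3, 131.3e-3, n = 3),
               -86.5e-3, tolerance = 1e-3)
  expect_error(ncx_equilibrium_potential(0.05, 0.1, n = 2), "singular")
})

test_that("physiological gradients place E_NCX in the -85 to -90 mV window", {
  # [Na+]_i = 15 mM, [Ca2+]_i = 80 nM, table extracellular values
  E_Na <- nernst_potential(0.135, 0.015)
  E_Ca <- nernst_potential(1.5e-3, 80e-9, valence = 2)
  E_NCX <- ncx_equilibrium_potential(E_Na, E_Ca)
  expect_lt(E_NCX, -85e-3)
  expect_gt(E_NCX, -90e-3)
  expect_equal(E_NCX, -86.7e-3, tolerance = 1e-2)
})

test_that("RT/F evaluates to about 26.7 mV at 310 K", {
  expect_equal(rtf310, 26.7e-3, tolerance = 1e-3)
})
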