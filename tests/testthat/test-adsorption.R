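test_that("surface coverage follows the site-blocking definition", {
  expect_equal(surface_coverage(3.027e-6, 3.027e-6), 0)
  expect_equal(surface_coverage(1e-12, 3.027e-6), 1, tolerance = 1e-6)
  # reference row: C = 2 uM, Ri = 2.895e-6, R0 = 3.027e-6 -> 0.0436
  expect_equal(round(surface_coverage(2.895e-6, 3.027e-6), 4), 0.0436)
  expect_warning(th <- surface_coverage(4e-6, 3e-6), "negative coverage")
  expect_lt(th, 0)
})

test_that("kinetic Langmuir fit recovers an exact model", {
  K <- 2e4
  C <- c(2, 2.5, 4, 6, 10) * 1e-6
  r0 <- 3.027e-6
  ri <- r0 * (1 - K * C / (1 + K * C))
  f <- langmuir_kinetic_fit(C, ri, r0)
  expect_equal(f$constant, K, tolerance = 1e-10)
  expect_equal(f$intercept, 1, tolerance = 1e-8)
  expect_identical(f$kind, "kinetic")
  expect_true(all(f$theta_series$theta >= 0 & f$theta_series$theta < 1))
})

test_that("kinetic fit equals the closed-form two-point slope on exact data", {
  K <- 5e4
  C <- c(3e-6, 8e-6)
  r0 <- 3e-6
  ri <- r0 * (1 - K * C / (1 + K * C))
  y <- r0 / (r0 - ri)
  slope2 <- diff(y) / diff(1 / C)
  # three points on the same exact line, fitted slope must equal it
  C3 <- c(C, 5e-6)
  ri3 <- r0 * (1 - K * C3 / (1 + K * C3))
  f <- langmuir_kinetic_fit(C3, ri3, r0)
  expect_equal(1 / f$constant, slope2, tolerance = 1e-10)
})

test_that("kinetic fit excludes uninhibited points with a warning", {
  K <- 2e4
  C <- c(1e-9, 2e-6, 4e-6, 8e-6)
  r0 <- 3e-6
  ri <- r0 * (1 - K * C / (1 + K * C))
  ri[1] <- r0  # no measurable inhibition -> infinite response
  expect_warning(f <- langmuir_kinetic_fit(C, ri, r0), "excluded")
  expect_equal(f$constant, K, tolerance = 1e-8)
  expect_identical(f$excluded, 1L)
  expect_error(
    suppressWarnings(langmuir_kinetic_fit(C[1:3], c(r0, r0, r0), r0)),
    "fewer than 3")
})

test_that("isotherm fit recovers an exact Langmuir model", {
  K <- 2e4
  C <- c(2, 3, 5, 8, 10) * 1e-6
  r0 <- 3.027e-6
  ri <- r0 * (1 - K * C / (1 + K * C))
  f <- langmuir_isotherm_fit(C, ri, r0)
  expect_equal(f$constant, K, tolerance = 1e-10)
  expect_equal(f$slope, 1, tolerance = 1e-8)
  expect_identical(f$kind, "isotherm")
  expect_error(langmuir_isotherm_fit(rep(2e-6, 4), ri[c(1, 1, 1, 1)], r0),
               "not distinct")
})

test_that("reference inhibition table yields the published adsorption constants", {
  inh <- com_inhibition_table()
  r0 <- attr(inh, "rate_control")
  kin <- langmuir_kinetic_fit(inh$conc, inh$rate, r0)
  iso <- langmuir_isotherm_fit(inh$conc, inh$rate, r0)
  expect_equal(kin$constant, 22646.6, tolerance = 1e-4)  # ~0.4% from 2.274e4
  expect_equal(iso$constant, 22859.2, tolerance = 1e-4)  # ~0.2% from 2.291e4
  expect_lt(abs(kin$constant - 2.274e4) / 2.274e4, 0.01)
  expect_lt(abs(iso$constant - 2.291e4) / 2.291e4, 0.01)
  expect_gt(kin$r_squared, 0.99)
  # coverage strictly increases with concentration on this series
  expect_true(all(diff(iso$theta_series$theta) > 0))
})

test_that("Gibbs free energy of adsorption follows its conventions", {
  # unit argument of the log: exactly zero
  expect_equal(gibbs_adsorption(1 / 55.5, 310), 0)
  # displaced-water convention reproduces the published value
  expect_equal(gibbs_adsorption(2.291e4, 310), -36.23, tolerance = 1e-3)
  # literal form without the 55.5 factor is ~10 kJ/mol less negative
  expect_equal(gibbs_adsorption(2.291e4, 310, water_molarity = 1), -25.87,
               tolerance = 1e-3)
  # strictly decreasing in K, linear in T
  ks <- c(1e3, 1e4, 1e5)
  expect_true(all(diff(gibbs_adsorption(ks, 310)) < 0))
  g1 <- gibbs_adsorption(2e4, 300); g2 <- gibbs_adsorption(2e4, 320)
  expect_equal(gibbs_adsorption(2e4, 310), (g1 + g2) / 2, tolerance = 1e-12)
  expect_error(gibbs_adsorption(-1, 310), "> 0")
})

test_that("kinetic and isotherm routes agree on noise-free model data", {
  # both linearizations invert the same Langmuir model exactly
  cfg <- synthetic_config(noise_cv = 0)
  inh <- generate_inhibition_table(cfg)
  r0 <- attr(inh, "ground_truth")$r0
  kl <- langmuir_kinetic_fit(inh$conc, inh$rate, r0)$constant
  ka <- langmuir_isotherm_fit(inh$conc, inh$rate, r0)$constant
  expect_lt(abs(kl - ka) / ka, 1e-8)
  # under measurement noise both routes still return positive, finite
  # constants of the right magnitude (quantitative recovery is bounded by
  # the 1/theta error amplification of the linearizations at low coverage)
  for (s in 1:25) {
    inh <- generate_inhibition_table(synthetic_config(rng_seed = s))
    kl <- suppressWarnings(
      langmuir_kinetic_fit(inh$conc, inh$rate, r0)$constant)
    ka <- suppressWarnings(
      langmuir_isotherm_fit(inh$conc, inh$rate, r0)$constant)
    expect_true(is.finite(kl) && kl > 0)
    expect_true(is.finite(ka) && ka > 0)
  }
})
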