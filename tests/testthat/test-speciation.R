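cc <- com_constants()

test_that("ionic strength matches hand-computed values and rejects bad input", {
  expect_equal(ionic_strength(c(0.15, 0.15), c(1, -1)), 0.15)
  expect_equal(ionic_strength(numeric(0), integer(0)), 0)
  expect_equal(ionic_strength(c(0.001, 0.002), c(2, -1)), 0.003)
  expect_error(ionic_strength(-0.1, 1), ">= 0")
  expect_error(ionic_strength(c(0.1, 0.1), 1), "equal length")
})

test_that("Davies log-gamma reproduces hand evaluation, limits, and symmetry", {
  expect_equal(davies_log_gamma(0, 0.15, 0.52), 0)
  expect_equal(davies_log_gamma(2, 0, 0.52), 0)
  expect_equal(davies_log_gamma(2, 0.15, 0.52), -0.4871, tolerance = 1e-4)
  # gamma depends on charge only through z^2
  for (I in c(0.01, 0.1, 0.3, 0.5)) {
    expect_identical(davies_log_gamma(2, I, 0.5215),
                     davies_log_gamma(-2, I, 0.5215))
    expect_gt(10^davies_log_gamma(2, I, 0.5215), 0)
    expect_lte(10^davies_log_gamma(2, I, 0.5215), 1)
  }
  expect_error(davies_log_gamma(2, -0.1, 0.52), ">= 0")
})

test_that("speciation with no active reactions returns totals as free", {
  cc0 <- cc
  cc0$reactions <- list()
  rec <- solution_recipe(1e-3, 2e-3, t_na = 5e-3, t_cl = 1e-3)
  st <- solve_speciation(rec, cc0)
  expect_true(st$converged)
  expect_equal(st$free[["Ca"]], 1e-3)
  expect_equal(st$free[["Ox"]], 2e-3)
  expect_equal(st$free[["Na"]], 5e-3)
})

test_that("as all logK -> -inf, free concentrations approach totals", {
  cc_off <- cc
  cc_off$reactions <- lapply(cc_off$reactions, function(r) { r$logK <- -20; r })
  rec <- solution_recipe(2e-4, 2e-4, t_na = 4e-4, t_cl = 4e-4)
  st <- solve_speciation(rec, cc_off)
  expect_equal(st$free[["Ca"]], 2e-4, tolerance = 1e-8)
  expect_equal(st$free[["Ox"]], 2e-4, tolerance = 1e-8)
})

test_that("converged states conserve mass and, in background mode, charge", {
  for (t_ca in c(1e-5, 1.791e-4, 1e-3)) {
    st <- solve_speciation(solution_recipe(t_ca, t_ca), cc)
    expect_true(st$converged)
    expect_lte(st$residuals[["mass"]], 1e-12)
    expect_lte(st$residuals[["charge"]], 1e-10)
    # ionic strength self-consistent with the target used for gamma
    z_all <- c(cc$species$charge[match(c("Ca", "Ox", "Na", "Cl", "H"),
                                       cc$species$name)],
               vapply(cc$reactions, `[[`, numeric(1), "charge"))
    expect_equal(ionic_strength(unname(st$free), z_all), 0.15,
                 tolerance = 1e-9)
    expect_true(all(st$free[c("Ca", "Ox", "Na", "Cl", "H")] > 0))
  }
})

test_that("activity-corrected mass-action law holds for every complex", {
  st <- solve_speciation(solution_recipe(1.791e-4, 1.791e-4), cc)
  a <- st$free * st$gamma
  a[["H"]] <- 10^(-6)  # pH fixes the H+ activity, not concentration
  for (r in cc$reactions) {
    lhs <- log10(a[[r$product]])
    rhs <- r$logK + sum(vapply(names(r$reactants), function(nm)
      r$reactants[[nm]] * log10(a[[nm]]), numeric(1)))
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("Newton solver matches the damped fixed-point oracle", {
  set.seed(42)
  n_ok <- 0L
  for (i in 1:100) {
    tot <- random_salt_totals()
    rec <- solution_recipe(tot[["Ca"]], tot[["Ox"]], pH = 6,
                           t_na = tot[["Na"]], t_cl = tot[["Cl"]])
    st <- solve_speciation(rec, cc)
    orc <- oracle_speciation(tot, pH = 6, constants = cc)
    for (X in c("Ca", "Ox", "Na", "Cl")) {
      expect_equal(st$free[[X]], orc$free[[X]], tolerance = 1e-6)
    }
    expect_equal(st$ionic_strength, orc$I, tolerance = 1e-6)
    expect_lte(st$residuals[["mass"]], 1e-12)
    n_ok <- n_ok + 1L
  }
  expect_identical(n_ok, 100L)
})

test_that("reference 1:1 recipe: free calcium near total, speciated sigma near printed", {
  st <- solve_speciation(solution_recipe(1.791e-4, 1.791e-4), cc)
  expect_lt(abs(st$free[["Ca"]] - 1.791e-4) / 1.791e-4, 0.15)
  sig <- relative_undersaturation(ion_product_sqrt(st),
                                  cc$physical$h0_sqrt)
  expect_lt(abs(sig - 0.10), 0.03)
})

test_that("ion product square root follows its definition and guards state", {
  st <- solve_speciation(solution_recipe(4e-4, 1e-4), cc)
  expect_equal(ion_product_sqrt(st),
               sqrt(st$free[["Ca"]] * st$free[["Ox"]]))
  st_eq <- solve_speciation(solution_recipe(2e-4, 2e-4), cc)
  expect_equal(ion_product_sqrt(st_eq), st_eq$free[["Ca"]],
               tolerance = 0.05) # equal totals give near-equal free ions
  bad <- st
  bad$converged <- FALSE
  expect_error(ion_product_sqrt(bad), "not converged")
})

test_that("degenerate zero-calcium recipe is a valid state, not an error", {
  st <- solve_speciation(solution_recipe(0, 1e-4), cc)
  expect_true(st$converged)
  expect_identical(st$free[["Ca"]], 0)
  expect_identical(ion_product_sqrt(st), 0)
})
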