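# Independent speciation oracle: damped fixed-point (successive
# substitution) on the mass balances, with the Davies correction inlined.
# Deliberately shares no code with the package's Newton solver.
oracle_speciation <- function(totals, pH, constants, tol = 1e-14,
                              max_inner = 20000L) {
  comps <- c("Ca", "Ox", "Na", "Cl")
  zc <- setNames(constants$species$charge, constants$species$name)
  a_h <- 10^(-pH)
  A <- constants$physical$debye_huckel_A
  lg10_gamma <- function(z, I) -A * z^2 * (sqrt(I) / (1 + sqrt(I)) - 0.3 * I)

  cplx_of <- function(free, I) {
    sapply(constants$reactions, function(r) {
      la <- r$logK
      for (nm in names(r$reactants)) {
        nu <- r$reactants[[nm]]
        a <- if (nm == "H") a_h else 10^lg10_gamma(zc[[nm]], I) * free[[nm]]
        if (a <= 0 && nu > 0) return(0)
        la <- la + nu * log10(a)
      }
      10^(la - lg10_gamma(r$charge, I))
    })
  }
  nu_of <- function(X) {
    sapply(constants$reactions, function(r) {
      if (X %in% names(r$reactants)) r$reactants[[X]] else 0
    })
  }
  nus <- lapply(setNames(comps, comps), nu_of)

  I <- 0.5 * sum(c(totals, a_h) * c(zc[comps], 1)^2)
  free <- totals
  for (outer in 1:100) {
    c_h <- a_h / 10^lg10_gamma(1, I)
    for (it in seq_len(max_inner)) {
      cpl <- cplx_of(free, I)
      recon <- vapply(comps, function(X) free[[X]] + sum(nus[[X]] * cpl),
                      numeric(1))
      err <- max(abs(recon - totals) / pmax(totals, 1e-300))
      if (err < tol) break
      upd <- totals / recon
      upd[totals == 0] <- 0
      free <- free * ifelse(free > 0, upd^0.7, 0)
    }
    zx <- sapply(constants$reactions, function(r) r$charge)
    I_new <- 0.5 * sum(c(free, c_h, cpl) * c(zc[comps], 1, zx)^2)
    if (abs(I_new - I) < 1e-12) { I <- I_new; break }
    I <- I_new
  }
  list(free = free, complexes = cpl, c_h = c_h, I = I)
}

# electroneutral random recipe composed from CaCl2 + Na2C2O4 + NaCl
random_salt_totals <- function() {
  x <- 10^stats::runif(3, -5, -2)
  c(Ca = x[1], Ox = x[2], Na = 2 * x[2] + x[3], Cl = 2 * x[1] + x[3])
}
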