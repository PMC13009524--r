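#' Ionic strength of a solution
#'
#' \eqn{I = \frac{1}{2}\sum_i c_i z_i^2} over all charged species.
#'
#' @param conc Numeric vector of species concentrations (mol dm^-3).
#' @param charge Integer vector of signed charges, same length as `conc`.
#' @return Ionic strength in mol dm^-3 (0 for an empty solution).
#' @examples
#' ionic_strength(c(0.15, 0.15), c(1, -1)) # 0.15 for a 1:1 salt
#' @export
ionic_strength <- function(conc, charge) {
  if (length(conc) != length(charge)) {
    stop("`conc` and `charge` must have equal length", call. = FALSE)
  }
  if (length(conc) == 0L) return(0)
  if (any(conc < 0)) stop("concentrations must be >= 0", call. = FALSE)
  0.5 * sum(conc * charge^2)
}

#' Davies activity coefficient (log10 scale)
#'
#' The Davies extension of Debye-Huckel theory,
#' \eqn{\log_{10}\gamma = -A z^2 (\sqrt I/(1+\sqrt I) - 0.3 I)},
#' valid up to roughly I = 0.5 mol dm^-3. Neutral species get
#' \eqn{\log\gamma = 0}.
#'
#' @param charge Signed integer charge (vectorized).
#' @param I Ionic strength, mol dm^-3.
#' @param A Debye-Huckel A parameter; default 0.5215 for water at 310.15 K.
#' @return log10 of the activity coefficient.
#' @examples
#' 10^davies_log_gamma(2, 0.15, 0.52) # ~0.326
#' @export
davies_log_gamma <- function(charge, I, A = 0.5215) {
  if (any(I < 0)) stop("ionic strength must be >= 0", call. = FALSE)
  if (any(A <= 0)) stop("Debye-Huckel A must be > 0", call. = FALSE)
  sI <- sqrt(I)
  -A * charge^2 * (sI / (1 + sI) - 0.3 * I)
}

#' Define a solution recipe for the speciation solver
#'
#' Total (analytical) concentrations of the Ca/oxalate/Na/Cl system. Two
#' modes are supported:
#' \describe{
#'   \item{background (default)}{`t_na`/`t_cl` are `NULL`; the solver
#'     determines the NaCl background from electroneutrality and the target
#'     ionic strength, mirroring the experimental practice of adjusting I
#'     with NaCl.}
#'   \item{explicit}{both `t_na` and `t_cl` are given; all four mass
#'     balances are solved and charge/I are reported, not enforced.}
#' }
#'
#' @param t_ca,t_ox Total calcium and oxalate, mol dm^-3.
#' @param pH Solution pH; fixes the H+ activity, `a_H = 10^-pH`.
#' @param temperature Kelvin.
#' @param target_ionic_strength Target I (mol dm^-3) for background mode.
#' @param t_na,t_cl Explicit sodium/chloride totals (mol dm^-3), or `NULL`.
#' @return An object of class `solution_recipe`.
#' @examples
#' solution_recipe(1.791e-4, 1.791e-4)
#' @export
solution_recipe <- function(t_ca, t_ox = t_ca, pH = 6,
                            temperature = 310.15,
                            target_ionic_strength = 0.15,
                            t_na = NULL, t_cl = NULL) {
  stopifnot(t_ca >= 0, t_ox >= 0, pH > 0, pH < 14, temperature > 0)
  explicit <- !is.null(t_na) && !is.null(t_cl)
  if (explicit) stopifnot(t_na >= 0, t_cl >= 0)
  totals <- c(Ca = t_ca, Ox = t_ox,
              Na = if (explicit) t_na else NA_real_,
              Cl = if (explicit) t_cl else NA_real_)
  structure(
    list(totals = totals, pH = pH, temperature = temperature,
         target_ionic_strength = if (explicit) NA_real_ else target_ionic_strength,
         mode = if (explicit) "explicit" else "background"),
    class = "solution_recipe"
  )
}

# concentrations of all complexes given free component concentrations,
# fixed H+ activity and per-charge activity coefficients (log10 scale)
.complex_conc <- function(c_comp, a_h, lg_of_z, constants) {
  out <- vapply(constants$reactions, function(r) {
    lg_a <- r$logK
    for (nm in names(r$reactants)) {
      nu <- r$reactants[[nm]]
      if (nm == "H") {
        lg_a <- lg_a + nu * log10(a_h)
      } else {
        cc <- c_comp[[nm]]
        if (cc <= 0) {
          if (nu > 0) return(0)
          stop("zero free concentration with negative stoichiometry: ", nm,
               call. = FALSE)
        }
        z <- .charge_of(nm, constants)
        lg_a <- lg_a + nu * (lg_of_z(z) + log10(cc))
      }
    }
    10^(lg_a - lg_of_z(r$charge))
  }, numeric(1))
  names(out) <- vapply(constants$reactions, `[[`, "", "product")
  out
}

.charge_of <- function(name, constants) {
  constants$species$charge[match(name, constants$species$name)]
}

# stoichiometry matrix: rows = reactions, columns = the four components
.stoich_matrix <- function(constants, comps) {
  nu <- matrix(0, nrow = length(constants$reactions), ncol = length(comps),
               dimnames = list(vapply(constants$reactions, `[[`, "", "product"),
                               comps))
  for (i in seq_along(constants$reactions)) {
    r <- constants$reactions[[i]]$reactants
    for (nm in intersect(names(r), comps)) nu[i, nm] <- r[[nm]]
  }
  nu
}

#' Solve aqueous speciation by Newton iteration on log-concentrations
#'
#' Computes free-ion concentrations of the Ca/oxalate/Na/Cl system from
#' total concentrations, via mass balance (and, in background mode,
#' electroneutrality plus a target-ionic-strength condition), with
#' activity-corrected mass-action laws for every configured complex and
#' Davies activity coefficients. The H+ activity is fixed by pH
#' (`[H+] = 10^-pH / gamma_1`). Newton iteration runs on log
#' concentrations (guaranteeing positivity) with an analytic Jacobian and
#' backtracking damping; in explicit-totals mode an outer loop re-estimates
#' the ionic strength and activity coefficients until self-consistent.
#'
#' @param recipe A [solution_recipe()].
#' @param constants A [com_constants()] object.
#' @param tol Relative convergence tolerance on every balance (default 1e-12).
#' @param max_iter Newton iteration cap per solve.
#' @return An object of class `speciation_state`: list with `free` (named
#'   vector over components, H, and complexes, mol dm^-3), `gamma` (activity
#'   coefficients per species), `ionic_strength`, `totals` (including the
#'   solved Na/Cl background), `converged`, `residuals` (max relative mass
#'   and charge balance errors), `iterations`, `pH`, `mode`.
#' @examples
#' st <- solve_speciation(solution_recipe(1.791e-4))
#' st$free[c("Ca", "Ox")]
#' @export
solve_speciation <- function(recipe, constants = com_constants(),
                             tol = 1e-12, max_iter = 200) {
  stopifnot(inherits(recipe, "solution_recipe"))
  comps <- c("Ca", "Ox", "Na", "Cl")
  z_comp <- vapply(comps, .charge_of, numeric(1), constants = constants)
  z_cplx <- vapply(constants$reactions, `[[`, numeric(1), "charge")
  nu <- .stoich_matrix(constants, comps)
  a_h <- 10^(-recipe$pH)
  A <- constants$physical$debye_huckel_A
  background <- recipe$mode == "background"

  totals <- recipe$totals
  # initial ionic-strength estimate (full dissociation)
  I <- if (background) recipe$target_ionic_strength else {
    ionic_strength(c(totals[comps], a_h), c(z_comp, 1))
  }
  if (background && I <= 0) stop("target ionic strength must be > 0", call. = FALSE)

  solve_at_gamma <- function(I_gamma) {
    lg_of_z <- function(z) davies_log_gamma(z, I_gamma, A)
    c_h <- a_h / 10^lg_of_z(1)
    # components solved by Newton: mass-balance comps with T > 0, plus
    # Na/Cl in background mode (charge + I equations)
    mb_comps <- comps[1:2][totals[1:2] > 0]
    unk <- if (background) c(mb_comps, "Na", "Cl") else comps[!is.na(totals) & totals > 0]
    if (!background) mb_comps <- unk
    fixed0 <- setdiff(comps, unk)

    c_comp <- setNames(numeric(4), comps)
    c_comp[mb_comps] <- totals[mb_comps]
    if (background) {
      I_rest <- ionic_strength(c(c_comp[c("Ca", "Ox")], c_h), c(2, -2, 1))
      q_rest <- sum(c_comp[c("Ca", "Ox")] * c(2, -2)) + c_h
      S <- 2 * (I - I_rest); D <- -q_rest
      if (S <= abs(D)) stop("target ionic strength too small for recipe", call. = FALSE)
      c_comp["Na"] <- (S + D) / 2
      c_comp["Cl"] <- (S - D) / 2
    }
    if (length(unk) == 0L) {
      cpl <- .complex_conc(as.list(c_comp), a_h, lg_of_z, constants)
      return(list(c_comp = c_comp, cpl = cpl, c_h = c_h, iter = 0L,
                  converged = TRUE, lg_of_z = lg_of_z))
    }

    resid_and_jac <- function(x) {
      c_comp[unk] <- exp(x)
      cpl <- .complex_conc(as.list(c_comp), a_h, lg_of_z, constants)
      f <- numeric(length(unk)); names(f) <- unk
      J <- matrix(0, length(unk), length(unk), dimnames = list(unk, unk))
      scale <- numeric(length(unk))
      tmax <- max(totals[mb_comps], a_h)
      for (X in mb_comps) {
        f[X] <- c_comp[X] + sum(nu[, X] * cpl) - totals[X]
        scale[match(X, unk)] <- tmax
        for (Y in unk) {
          J[X, Y] <- (X == Y) * c_comp[X] + sum(nu[, X] * nu[, Y] * cpl)
        }
      }
      if (background) {
        allz <- c(z_comp, 1, z_cplx)
        allc <- c(c_comp, c_h, cpl)
        f["Na"] <- sum(allz * allc)                    # electroneutrality
        f["Cl"] <- 0.5 * sum(allz^2 * allc) - I        # target ionic strength
        scale[match("Na", unk)] <- sum(abs(allz) * allc)
        scale[match("Cl", unk)] <- I
        for (Y in unk) {
          zY <- z_comp[Y]
          J["Na", Y] <- zY * c_comp[Y] + sum(z_cplx * nu[, Y] * cpl)
          J["Cl", Y] <- 0.5 * (zY^2 * c_comp[Y] + sum(z_cplx^2 * nu[, Y] * cpl))
        }
      }
      list(f = f, J = J, scaled = max(abs(f) / scale), c_comp = c_comp, cpl = cpl)
    }

    x <- log(c_comp[unk])
    st <- resid_and_jac(x)
    iter <- 0L
    while (st$scaled > tol && iter < max_iter) {
      iter <- iter + 1L
      step <- tryCatch(solve(st$J, st$f), error = function(e) {
        stop("speciation Jacobian singular (degenerate system)", call. = FALSE)
      })
      step <- pmin(pmax(step, -2), 2)
      lam <- 1
      repeat {
        cand <- tryCatch(resid_and_jac(x - lam * step), error = function(e) NULL)
        if (!is.null(cand) && cand$scaled <= st$scaled) break
        if (lam < 1e-4) break
        lam <- lam / 2
      }
      if (is.null(cand)) {
        stop("speciation Newton step failed to make progress", call. = FALSE)
      }
      x <- x - lam * step
      st <- cand
    }
    list(c_comp = st$c_comp, cpl = st$cpl, c_h = c_h, iter = iter,
         converged = st$scaled <= tol, lg_of_z = lg_of_z, scaled = st$scaled)
  }

  if (background) {
    sol <- solve_at_gamma(I)   # gamma at target I is self-consistent by construction
    outer <- 1L
  } else {
    outer <- 0L
    repeat {
      outer <- outer + 1L
      sol <- solve_at_gamma(I)
      I_new <- ionic_strength(c(sol$c_comp, sol$c_h, sol$cpl),
                              c(z_comp, 1, z_cplx))
      if (abs(I_new - I) <= 1e-9 || outer >= 50L) { I <- I_new; break }
      I <- I_new
    }
  }

  c_comp <- sol$c_comp; cpl <- sol$cpl
  totals_out <- totals
  if (background) {
    totals_out["Na"] <- c_comp["Na"] + sum(nu[, "Na"] * cpl)
    totals_out["Cl"] <- c_comp["Cl"] + sum(nu[, "Cl"] * cpl)
  }
  recon <- vapply(comps, function(X) c_comp[[X]] + sum(nu[, X] * cpl), numeric(1))
  mb_res <- max(abs(recon - totals_out) / max(totals_out, a_h))
  allz <- c(z_comp, 1, z_cplx)
  allc <- c(c_comp, H = unname(sol$c_h), cpl)
  q_res <- abs(sum(allz * allc)) / sum(abs(allz) * allc)
  I_final <- if (background) I else ionic_strength(allc, allz)
  gamma <- 10^sol$lg_of_z(allz)
  names(gamma) <- names(allc)

  if (!sol$converged) {
    stop(sprintf(
      "speciation failed to converge in %d iterations (max scaled residual %.3e)",
      max_iter, sol$scaled), call. = FALSE)
  }
  structure(
    list(free = allc, gamma = gamma, ionic_strength = unname(I_final),
         totals = totals_out, converged = sol$converged,
         residuals = c(mass = unname(mb_res), charge = unname(q_res)),
         iterations = sol$iter, pH = recipe$pH,
         temperature = recipe$temperature, mode = recipe$mode),
    class = "speciation_state"
  )
}

#' @export
print.speciation_state <- function(x, ...) {
  cat(sprintf("Speciation state (%s mode), I = %.4g mol dm^-3, %s\n",
              x$mode, x$ionic_strength,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  free [Ca2+] = %.6g  [C2O4 2-] = %.6g mol dm^-3\n",
              x$free[["Ca"]], x$free[["Ox"]]))
  cat(sprintf("  residuals: mass %.2e, charge %.2e\n",
              x$residuals[["mass"]], x$residuals[["charge"]]))
  invisible(x)
}

#' Square root of the free-ion concentration product
#'
#' \eqn{H^{1/2} = \sqrt{[\mathrm{Ca}^{2+}][\mathrm{C_2O_4^{2-}}]}}, the
#' quantity compared against the solubility value \eqn{H_0^{1/2}} in the
#' relative undersaturation.
#'
#' @param state A converged [solve_speciation()] result.
#' @return mol dm^-3.
#' @export
ion_product_sqrt <- function(state) {
  stopifnot(inherits(state, "speciation_state"))
  if (!isTRUE(state$converged)) {
    stop("speciation state is not converged", call. = FALSE)
  }
  sqrt(state$free[["Ca"]] * state$free[["Ox"]])
}
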