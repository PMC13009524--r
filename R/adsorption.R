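#' Surface coverage from rate reduction
#'
#' Under site-blocking inhibition \eqn{R_i = R_0 (1 - \theta)}, the
#' fractional coverage of active dissolution sites is
#' \eqn{\theta = 1 - R_i / R_0}.
#'
#' @param rate_inhibited Rate with additive, mol m^-2 min^-1 (vectorized).
#' @param rate_control Control rate \eqn{R_0}.
#' @return \eqn{\theta} in \[0, 1); negative values (promotion) are flagged
#'   with a warning.
#' @examples
#' surface_coverage(2.895e-6, 3.027e-6) # ~0.044
#' @export
surface_coverage <- function(rate_inhibited, rate_control) {
  if (any(rate_control <= 0)) stop("control rate must be > 0", call. = FALSE)
  if (any(rate_inhibited <= 0)) stop("inhibited rate must be > 0", call. = FALSE)
  theta <- 1 - rate_inhibited / rate_control
  if (any(theta < 0)) {
    warning("negative coverage (rate above control) flagged", call. = FALSE)
  }
  theta
}

.langmuir_result <- function(constant, slope, intercept, r_squared, kind,
                             conc, theta, fit, delta_g = NULL,
                             excluded = integer(0)) {
  structure(
    list(constant = constant, slope = slope, intercept = intercept,
         r_squared = r_squared, kind = kind,
         theta_series = data.frame(conc = conc, theta = theta),
         delta_g = delta_g, fit = fit, excluded = excluded),
    class = "langmuir_fit"
  )
}

#' Kinetic Langmuir fit of inhibition data
#'
#' Linearized kinetic Langmuir isotherm: when an inhibitor blocks a
#' fraction \eqn{\theta = K_L C/(1+K_L C)} of active sites,
#' \eqn{R_0/(R_0 - R_i) = 1 + 1/(K_L C)}. Ordinary least squares of
#' \eqn{y = R_0/(R_0 - R_i)} on \eqn{x = 1/C} gives the affinity constant
#' \eqn{K_L = 1/\mathrm{slope}}; the ideal intercept is 1.
#'
#' Points with \eqn{R_i = R_0} (infinite response) are excluded with a
#' warning.
#'
#' @param conc Inhibitor concentrations, mol dm^-3 (distinct, > 0).
#' @param rate Inhibited rates \eqn{R_i}, mol m^-2 min^-1.
#' @param rate_control Control rate \eqn{R_0}.
#' @return A `langmuir_fit` (kind `"kinetic"`) with `constant` = \eqn{K_L}
#'   in dm^3 mol^-1, `slope`, `intercept`, `r_squared`, `theta_series`.
#' @examples
#' C <- c(2, 5, 10) * 1e-6
#' th <- 2e4 * C / (1 + 2e4 * C)
#' langmuir_kinetic_fit(C, 3e-6 * (1 - th), 3e-6)$constant # 2e4
#' @export
langmuir_kinetic_fit <- function(conc, rate, rate_control) {
  stopifnot(length(conc) == length(rate))
  if (any(conc <= 0)) stop("inhibitor concentrations must be > 0", call. = FALSE)
  usable <- rate < rate_control
  if (any(!usable)) {
    warning(sum(!usable), " point(s) with rate >= control excluded from ",
            "kinetic Langmuir fit", call. = FALSE)
  }
  if (sum(usable) < 3) stop("fewer than 3 usable points", call. = FALSE)
  x <- 1 / conc[usable]
  if (isTRUE(all.equal(min(x), max(x)))) {
    stop("degenerate fit: concentrations not distinct", call. = FALSE)
  }
  y <- rate_control / (rate_control - rate[usable])
  fit <- lm(y ~ x)
  sl <- unname(coef(fit)[2])
  if (sl <= 0) stop("non-positive slope: data inconsistent with Langmuir ",
                    "blocking", call. = FALSE)
  .langmuir_result(1 / sl, sl, unname(coef(fit)[1]),
                   .quiet_summary(fit)$r.squared, "kinetic",
                   conc, surface_coverage(pmin(rate, rate_control), rate_control),
                   fit, excluded = which(!usable))
}

#' Equilibrium Langmuir isotherm fit
#'
#' Linearized adsorption isotherm \eqn{C_i/\theta = C_i + 1/K_{ads}}:
#' ordinary least squares of \eqn{C_i/\theta} on \eqn{C_i} gives the
#' adsorption equilibrium constant \eqn{K_{ads} = 1/\mathrm{intercept}};
#' the ideal slope is 1. Coverage \eqn{\theta} is recomputed from the rates
#' via [surface_coverage()]; points with \eqn{\theta = 0} are excluded with
#' a warning. The Gibbs free energy of adsorption is attached via
#' [gibbs_adsorption()].
#'
#' @inheritParams langmuir_kinetic_fit
#' @param temperature Kelvin (default 310).
#' @param water_molarity Standard-state water molarity for the Gibbs
#'   energy, mol dm^-3 (default 55.5; use 1 for the literal
#'   \eqn{-RT\ln K_{ads}} form).
#' @param gas_constant J mol^-1 K^-1.
#' @return A `langmuir_fit` (kind `"isotherm"`) with `constant` =
#'   \eqn{K_{ads}} in dm^3 mol^-1 and `delta_g` in kJ mol^-1.
#' @export
langmuir_isotherm_fit <- function(conc, rate, rate_control,
                                  temperature = 310, water_molarity = 55.5,
                                  gas_constant = 8.314) {
  stopifnot(length(conc) == length(rate))
  if (any(conc <= 0)) stop("inhibitor concentrations must be > 0", call. = FALSE)
  theta <- surface_coverage(rate, rate_control)
  usable <- theta > 0
  if (any(!usable)) {
    warning(sum(!usable), " point(s) with zero/negative coverage excluded ",
            "from isotherm fit", call. = FALSE)
  }
  if (sum(usable) < 3) stop("fewer than 3 usable points", call. = FALSE)
  x <- conc[usable]
  if (isTRUE(all.equal(min(x), max(x)))) {
    stop("degenerate fit: concentrations not distinct", call. = FALSE)
  }
  y <- x / theta[usable]
  fit <- lm(y ~ x)
  ic <- unname(coef(fit)[1])
  if (ic <= 0) stop("non-positive intercept: data inconsistent with a ",
                    "Langmuir isotherm", call. = FALSE)
  k_ads <- 1 / ic
  .langmuir_result(k_ads, unname(coef(fit)[2]), ic,
                   .quiet_summary(fit)$r.squared, "isotherm", conc, theta, fit,
                   delta_g = gibbs_adsorption(k_ads, temperature,
                                              water_molarity, gas_constant),
                   excluded = which(!usable))
}

#' @export
print.langmuir_fit <- function(x, ...) {
  lab <- if (x$kind == "kinetic") "K_L (affinity)" else "K_ads (equilibrium)"
  cat(sprintf("Langmuir %s fit, %d points\n", x$kind, nrow(x$theta_series)))
  cat(sprintf("  %s = %.4g dm^3 mol^-1\n", lab, x$constant))
  cat(sprintf("  slope = %.4f, intercept = %.4g, r^2 = %.4f\n",
              x$slope, x$intercept, x$r_squared))
  if (!is.null(x$delta_g)) {
    cat(sprintf("  delta-G(ads) = %.3f kJ mol^-1\n", x$delta_g))
  }
  invisible(x)
}

#' Gibbs free energy of adsorption
#'
#' \eqn{\Delta G_{ads} = -RT \ln(n_w K_{ads})} in kJ mol^-1, where
#' \eqn{n_w} is the standard-state water molarity (55.5 mol dm^-3 by the
#' displaced-solvent convention when \eqn{K_{ads}} is in dm^3 mol^-1; set
#' `water_molarity = 1` for the literal \eqn{-RT\ln K_{ads}} form, which
#' gives a value about 10 kJ mol^-1 less negative).
#'
#' @param k_ads Adsorption equilibrium constant, dm^3 mol^-1.
#' @param temperature Kelvin.
#' @param water_molarity mol dm^-3 (default 55.5).
#' @param gas_constant J mol^-1 K^-1 (default 8.314).
#' @return kJ mol^-1; negative for favorable adsorption when
#'   `water_molarity * k_ads > 1`.
#' @examples
#' gibbs_adsorption(2.291e4, 310) # ~ -36.2 kJ/mol
#' @export
gibbs_adsorption <- function(k_ads, temperature = 310, water_molarity = 55.5,
                             gas_constant = 8.314) {
  if (any(k_ads <= 0) || any(temperature <= 0) || any(water_molarity <= 0)) {
    stop("k_ads, temperature and water_molarity must be > 0", call. = FALSE)
  }
  -gas_constant * temperature * log(water_molarity * k_ads) / 1000
}
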