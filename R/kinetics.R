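# summary.lm warns on machine-precision fits; exact synthetic data hit that
# legitimately, so muffle only this message
.quiet_summary <- function(fit) {
  withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

#' Relative undersaturation of a sparingly soluble salt
#'
#' \eqn{\sigma = (H_0^{1/2} - H^{1/2}) / H_0^{1/2}}, the normalized driving
#' force for dissolution: 0 at saturation, 1 in pure solvent. `h_sqrt` is
#' the square root of the free-ion concentration product
#' \eqn{\sqrt{[\mathrm{Ca}^{2+}][\mathrm{C_2O_4^{2-}}]}} and `h0_sqrt` its
#' value at equilibrium (the solubility at the working ionic strength).
#'
#' @param h_sqrt Solution value of \eqn{H^{1/2}}, mol dm^-3 (vectorized).
#' @param h0_sqrt Solubility \eqn{H_0^{1/2}}, mol dm^-3; default 1.994e-4,
#'   the COM value at I = 0.15 mol dm^-3 and 37 C.
#' @return Dimensionless value in \[0, 1\].
#' @examples
#' relative_undersaturation(1.791e-4) # ~0.102, a 1:1 COM dissolution point
#' @export
relative_undersaturation <- function(h_sqrt, h0_sqrt = 1.994e-4) {
  if (any(h0_sqrt <= 0)) stop("h0_sqrt must be > 0", call. = FALSE)
  if (any(h_sqrt < 0)) stop("h_sqrt must be >= 0", call. = FALSE)
  if (any(h_sqrt > h0_sqrt)) {
    stop("supersaturated solution (h_sqrt > h0_sqrt): dissolution model ",
         "inapplicable", call. = FALSE)
  }
  (h0_sqrt - h_sqrt) / h0_sqrt
}

#' Relative undersaturation from total concentrations
#'
#' Convenience wrapper computing \eqn{\sigma} from total calcium/oxalate
#' molarities. In `"total"` mode (default) \eqn{H^{1/2} =
#' \sqrt{T_{Ca} T_{Ox}}}, which reproduces the reference dissolution tables
#' exactly; in `"speciated"` mode the free-ion product comes from
#' [solve_speciation()]. The mode is recorded as an attribute.
#'
#' @param t_ca,t_ox Total molarities, mol dm^-3.
#' @param mode `"total"` or `"speciated"`.
#' @param h0_sqrt Solubility \eqn{H_0^{1/2}}, mol dm^-3.
#' @param constants [com_constants()] set (speciated mode).
#' @param pH,temperature,target_ionic_strength Solution conditions passed to
#'   [solution_recipe()] in speciated mode.
#' @return Numeric vector of \eqn{\sigma} with attribute `mode`.
#' @export
com_sigma <- function(t_ca, t_ox = t_ca, mode = c("total", "speciated"),
                      h0_sqrt = 1.994e-4, constants = com_constants(),
                      pH = 6, temperature = 310.15,
                      target_ionic_strength = 0.15) {
  mode <- match.arg(mode)
  h <- if (mode == "total") {
    sqrt(t_ca * t_ox)
  } else {
    mapply(function(ca, ox) {
      st <- solve_speciation(
        solution_recipe(ca, ox, pH = pH, temperature = temperature,
                        target_ionic_strength = target_ionic_strength),
        constants = constants)
      ion_product_sqrt(st)
    }, t_ca, t_ox)
  }
  structure(relative_undersaturation(h, h0_sqrt), mode = mode)
}

#' Assemble a dissolution run
#'
#' A run is an ordered set of (sigma, rate) points sharing conditions --
#' one linearized series of the log-log rate-law plot.
#'
#' @param sigma Relative undersaturations, in \[0, 1).
#' @param rate Surface-normalized dissolution rates, mol m^-2 min^-1.
#' @param seed_mg Seed crystal mass, mg.
#' @param rpm Stirring speed (recorded; the rate law is stirring-independent
#'   for surface-controlled dissolution and the fit ignores it).
#' @param inhibitor_molar Additive concentration, mol dm^-3 (0 = control).
#' @param label Series label, e.g. `"control"` or `"additive"`.
#' @param t_ca Optional total calcium per point, mol dm^-3.
#' @param temperature,pH,ionic_strength Shared conditions, stored as
#'   attributes.
#' @return A `dissolution_run`: a data.frame with one row per point.
#' @export
dissolution_run <- function(sigma, rate, seed_mg = 10, rpm = 300,
                            inhibitor_molar = 0, label = "control",
                            t_ca = NA_real_, temperature = 310.15, pH = 6,
                            ionic_strength = 0.15) {
  stopifnot(length(sigma) == length(rate))
  if (any(sigma < 0 | sigma >= 1)) {
    stop("sigma must lie in [0, 1)", call. = FALSE)
  }
  if (any(rate <= 0)) stop("rates must be > 0", call. = FALSE)
  if (any(seed_mg <= 0)) stop("seed mass must be > 0", call. = FALSE)
  out <- data.frame(sigma = sigma, rate = rate, t_ca = t_ca,
                    seed_mg = seed_mg, rpm = rpm,
                    inhibitor_molar = inhibitor_molar, label = label)
  structure(out, class = c("dissolution_run", "data.frame"),
            temperature = temperature, pH = pH,
            ionic_strength = ionic_strength)
}

#' Fit the power dissolution rate law
#'
#' Fits \eqn{R = k s \sigma^n} (with the site factor \eqn{s} normalized to
#' 1) by ordinary least squares in log-log space: \eqn{\log_{10} R} on
#' \eqn{\log_{10}\sigma}. The apparent reaction order \eqn{n} is the slope
#' and the intrinsic rate constant \eqn{k = 10^{\mathrm{intercept}}}.
#' An order near 2 is conventionally read as surface-controlled
#' dissolution.
#'
#' @param run A [dissolution_run()] (or data.frame with `sigma`, `rate`),
#'   at least 3 points, all positive.
#' @return A `rate_law_fit`: list with `n`, `k`, `n_rounded`, `s` (fixed 1),
#'   `r_squared`, `se_slope`, `se_intercept`, `n_points`, `label`, and the
#'   underlying `lm` object as `fit`.
#' @examples
#' run <- dissolution_run(sigma = c(0.1, 0.2, 0.3),
#'                        rate = 1e-4 * c(0.1, 0.2, 0.3)^2)
#' fit_rate_law(run)
#' @export
fit_rate_law <- function(run) {
  sigma <- run$sigma; rate <- run$rate
  if (length(sigma) < 3) stop("need >= 3 points to fit the rate law", call. = FALSE)
  if (any(sigma <= 0) || any(rate <= 0)) {
    stop("sigma and rate must be > 0 for the log-log fit", call. = FALSE)
  }
  if (isTRUE(all.equal(min(sigma), max(sigma)))) {
    stop("degenerate fit: sigma has no variance", call. = FALSE)
  }
  fit <- lm(log10(rate) ~ log10(sigma))
  sm <- .quiet_summary(fit)
  n <- unname(coef(fit)[2]); b <- unname(coef(fit)[1])
  structure(
    list(n = n, k = 10^b, n_rounded = round(n), s = 1,
         r_squared = sm$r.squared,
         se_slope = sm$coefficients[2, 2],
         se_intercept = sm$coefficients[1, 2],
         n_points = length(sigma),
         label = if (!is.null(run$label)) run$label[1] else NA_character_,
         fit = fit),
    class = "rate_law_fit"
  )
}

#' @export
print.rate_law_fit <- function(x, ...) {
  cat(sprintf("Power rate law R = k * sigma^n  [%s, %d points]\n",
              x$label, x$n_points))
  cat(sprintf("  n = %.4f (se %.4f), rounds to %d\n", x$n, x$se_slope, x$n_rounded))
  cat(sprintf("  k = %.4g mol m^-2 min^-1 (log10 se %.4f)\n", x$k, x$se_intercept))
  cat(sprintf("  r^2 = %.4f\n", x$r_squared))
  invisible(x)
}

#' Build a constant-composition titration trace
#'
#' Cumulative titrant-volume record from a constant-composition dissolution
#' experiment: titrant additions hold the solution composition fixed, so
#' the addition rate measures the dissolution rate.
#'
#' @param time_min Sampling times, minutes, strictly increasing.
#' @param volume_cm3 Cumulative titrant volume, cm^3, non-decreasing.
#' @param titrant_conc Titrant concentration, mol dm^-3.
#' @param seed_mg Seed crystal mass, mg.
#' @param ssa Specific surface area of the seed, m^2 g^-1 (BET); default
#'   3.73.
#' @return A `titration_trace` object.
#' @export
titration_trace <- function(time_min, volume_cm3, titrant_conc,
                            seed_mg, ssa = 3.73) {
  stopifnot(length(time_min) == length(volume_cm3))
  if (length(time_min) < 2) stop("need >= 2 samples", call. = FALSE)
  if (any(diff(time_min) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (any(diff(volume_cm3) < 0)) {
    stop("titrant volume must be non-decreasing", call. = FALSE)
  }
  stopifnot(titrant_conc > 0, seed_mg > 0, ssa > 0)
  structure(
    list(time_min = time_min, volume_cm3 = volume_cm3,
         titrant_conc = titrant_conc, seed_mg = seed_mg, ssa = ssa),
    class = "titration_trace"
  )
}

#' Extract a surface-normalized dissolution rate from a titration trace
#'
#' Least-squares slope of moles-of-titrant-added versus time over the
#' steady segment, normalized by the seed surface area
#' (seed mass x BET specific surface area):
#' \eqn{R = (dn/dt) / (m \cdot \mathrm{SSA})} in mol m^-2 min^-1.
#'
#' @param trace A [titration_trace()].
#' @param burn_in Fraction of the initial record to discard before fitting
#'   (default 0 = fit the full trace).
#' @return Rate in mol m^-2 min^-1 (positive for dissolution).
#' @export
rate_from_titration <- function(trace, burn_in = 0) {
  stopifnot(inherits(trace, "titration_trace"), burn_in >= 0, burn_in < 1)
  keep <- trace$time_min >= burn_in * max(trace$time_min)
  t <- trace$time_min[keep]
  moles <- trace$titrant_conc * trace$volume_cm3[keep] * 1e-3  # cm^3 -> dm^3
  if (length(t) < 2) stop("fewer than 2 points after burn-in", call. = FALSE)
  slope <- unname(coef(lm(moles ~ t))[2])
  area_m2 <- trace$seed_mg * 1e-3 * trace$ssa
  slope / area_m2
}

#' Percent inhibition of the dissolution rate
#'
#' \eqn{100 (R_0 - R_i)/R_0}: the fractional rate reduction caused by an
#' adsorbing additive, in percent. A rate above the control (promotion) is
#' reported as a negative value with a warning, not an error.
#'
#' @param rate_control Control rate \eqn{R_0}, mol m^-2 min^-1 (> 0).
#' @param rate_inhibited Rate with additive \eqn{R_i} (vectorized).
#' @return Percent in (-Inf, 100).
#' @examples
#' percent_inhibition(3.027e-6, 2.466e-6) # ~18.5 %
#' @export
percent_inhibition <- function(rate_control, rate_inhibited) {
  if (any(rate_control <= 0)) stop("control rate must be > 0", call. = FALSE)
  if (any(rate_inhibited <= 0)) stop("inhibited rate must be > 0", call. = FALSE)
  if (any(rate_inhibited > rate_control)) {
    warning("rate above control: promotion reported as negative inhibition",
            call. = FALSE)
  }
  100 * (rate_control - rate_inhibited) / rate_control
}
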