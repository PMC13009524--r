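# run expr with a locally seeded RNG, restoring the caller's stream
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Configuration for the synthetic dissolution-experiment generator
#'
#' Ground-truth parameters and design grids for simulated
#' constant-composition dissolution experiments. The defaults clone the
#' reference study design: a power-law rate with order 2 and the reported
#' control rate constant, a Langmuir blocking affinity of 2.274e4
#' dm^3 mol^-1, an 8-point undersaturation grid spanning 0.10-0.28, an
#' 11-point inhibitor grid spanning 2-10 uM, and 2% multiplicative noise.
#'
#' @param k_true Rate constant, mol m^-2 min^-1.
#' @param n_true Apparent reaction order.
#' @param kl_true Langmuir affinity constant, dm^3 mol^-1.
#' @param h0_sqrt Solubility \eqn{H_0^{1/2}}, mol dm^-3.
#' @param sigma_grid Relative undersaturations, each in (0, 1).
#' @param conc_grid Inhibitor concentrations, mol dm^-3.
#' @param noise_cv Relative multiplicative (log-normal) noise; 0 = exact.
#' @param rng_seed Integer seed; generators are bit-reproducible given it.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(k_true = 4.769e-5, n_true = 2,
                             kl_true = 2.274e4, h0_sqrt = 1.994e-4,
                             sigma_grid = c(0.10, 0.12, 0.15, 0.17,
                                            0.20, 0.25, 0.27, 0.28),
                             conc_grid = c(2, 2.22, 2.5, 3, 4, 5,
                                           6, 7, 8, 9, 10) * 1e-6,
                             noise_cv = 0.02, rng_seed = 1L) {
  stopifnot(k_true > 0, n_true > 0, kl_true > 0, h0_sqrt > 0,
            noise_cv >= 0, length(sigma_grid) > 0, length(conc_grid) > 0)
  if (any(sigma_grid <= 0 | sigma_grid >= 1)) {
    stop("sigma_grid values must lie in (0, 1)", call. = FALSE)
  }
  if (any(conc_grid <= 0)) stop("conc_grid values must be > 0", call. = FALSE)
  structure(
    list(k_true = k_true, n_true = n_true, kl_true = kl_true,
         h0_sqrt = h0_sqrt, sigma_grid = sigma_grid, conc_grid = conc_grid,
         noise_cv = noise_cv, rng_seed = as.integer(rng_seed)),
    class = "synthetic_config"
  )
}

#' Generate a synthetic dissolution run
#'
#' One rate point per grid undersaturation, drawn from the power rate law
#' \eqn{R = k_{true}\,\sigma^{n_{true}} e^\varepsilon} with
#' \eqn{\varepsilon \sim N(0, \mathrm{noise\_cv})}. With `noise_cv = 0`
#' the data are exact and [fit_rate_law()] recovers the inputs to machine
#' precision.
#'
#' @param config A [synthetic_config()].
#' @param label Series label for the run.
#' @return A [dissolution_run()] with attribute `ground_truth`.
#' @examples
#' run <- generate_rate_table(synthetic_config(noise_cv = 0))
#' fit_rate_law(run)$n # 2
#' @export
generate_rate_table <- function(config, label = "synthetic") {
  stopifnot(inherits(config, "synthetic_config"))
  eps <- .with_seed(config$rng_seed,
                    rnorm(length(config$sigma_grid), 0, 1)) * config$noise_cv
  rate <- config$k_true * config$sigma_grid^config$n_true * exp(eps)
  run <- dissolution_run(sigma = config$sigma_grid, rate = rate,
                         t_ca = config$h0_sqrt * (1 - config$sigma_grid),
                         label = label)
  attr(run, "ground_truth") <- list(k = config$k_true, n = config$n_true)
  run
}

#' Generate a synthetic inhibition series
#'
#' Langmuir site blocking: coverage \eqn{\theta = K_L C/(1+K_L C)} and
#' \eqn{R_i = R_0 (1-\theta) e^\varepsilon}. Coverage is strictly
#' increasing in concentration; \eqn{R_i \to R_0} as \eqn{C \to 0}.
#'
#' @param config A [synthetic_config()].
#' @param r0 Control rate \eqn{R_0}, mol m^-2 min^-1 (default 3.027e-6,
#'   the reference control rate at \eqn{\sigma = 0.20}).
#' @return data.frame with `conc`, `rate`, `theta_true`, plus attribute
#'   `ground_truth` (`kl`, `r0`).
#' @export
generate_inhibition_table <- function(config, r0 = 3.027e-6) {
  stopifnot(inherits(config, "synthetic_config"), r0 > 0)
  C <- config$conc_grid
  theta <- config$kl_true * C / (1 + config$kl_true * C)
  eps <- .with_seed(config$rng_seed + 1L,
                    rnorm(length(C), 0, 1)) * config$noise_cv
  out <- data.frame(conc = C, rate = r0 * (1 - theta) * exp(eps),
                    theta_true = theta)
  attr(out, "ground_truth") <- list(kl = config$kl_true, r0 = r0)
  out
}

#' Generate a synthetic constant-composition titration trace
#'
#' Cumulative titrant volume whose mean slope encodes the requested
#' surface-normalized rate: \eqn{dV/dt = R\,m\,\mathrm{SSA}/c_{titrant}}.
#' Multiplicative noise is applied to the per-interval increments so the
#' volume stays non-decreasing. A noise-free trace round-trips through
#' [rate_from_titration()] exactly.
#'
#' @param rate Surface-normalized dissolution rate, mol m^-2 min^-1
#'   (0 gives a flat trace).
#' @param seed_mg Seed mass, mg.
#' @param ssa BET specific surface area, m^2 g^-1.
#' @param titrant_conc Titrant concentration, mol dm^-3 (> 0).
#' @param duration Total duration, min.
#' @param interval Sampling interval, min (must divide `duration`).
#' @param noise_cv Relative noise on volume increments.
#' @param rng_seed Integer seed.
#' @return A [titration_trace()].
#' @export
generate_titration_series <- function(rate, seed_mg = 10, ssa = 3.73,
                                      titrant_conc = 0.01, duration = 60,
                                      interval = 1, noise_cv = 0,
                                      rng_seed = 1L) {
  stopifnot(rate >= 0, seed_mg > 0, ssa > 0, duration > 0, interval > 0,
            noise_cv >= 0)
  if (titrant_conc <= 0) stop("titrant concentration must be > 0", call. = FALSE)
  n_step <- duration / interval
  if (abs(n_step - round(n_step)) > 1e-9) {
    stop("interval must divide duration", call. = FALSE)
  }
  n_step <- round(n_step)
  area_m2 <- seed_mg * 1e-3 * ssa
  dv <- rate * area_m2 / titrant_conc * 1e3 * interval   # dm^3 -> cm^3
  eps <- .with_seed(rng_seed, rnorm(n_step, 0, 1)) * noise_cv
  increments <- dv * exp(eps)
  titration_trace(time_min = seq(0, duration, by = interval),
                  volume_cm3 = c(0, cumsum(increments)),
                  titrant_conc = titrant_conc, seed_mg = seed_mg, ssa = ssa)
}
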