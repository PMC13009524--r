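#' Read a dissolution-run CSV
#'
#' Expected columns: `t_ca_molar`, optional `sigma`, `rate`, `seed_mg`,
#' `rpm`, `inhibitor_molar`, `label`. Lines starting with `#` are comments.
#' When `sigma` is absent (or `recompute_sigma = TRUE`) it is computed from
#' `t_ca_molar` via the relative undersaturation with the configured
#' \eqn{H_0^{1/2}}; a run fixture may carry rounded published sigmas, so
#' recomputation is the full-precision route.
#'
#' @param path CSV file path.
#' @param h0_sqrt Solubility \eqn{H_0^{1/2}}, mol dm^-3.
#' @param recompute_sigma Replace any stored `sigma` column from
#'   `t_ca_molar` (default `FALSE`: stored values are kept when present).
#' @return A list of [dissolution_run()] objects, one per `label`.
#' @export
read_dissolution_csv <- function(path, h0_sqrt = 1.994e-4,
                                 recompute_sigma = FALSE) {
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("t_ca_molar", "rate", "label")
  if (!all(need %in% names(df))) {
    stop("run CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!"sigma" %in% names(df) || recompute_sigma) {
    df$sigma <- as.numeric(com_sigma(df$t_ca_molar, h0_sqrt = h0_sqrt))
  }
  lapply(split(df, df$label), function(d) {
    dissolution_run(sigma = d$sigma, rate = d$rate,
                    seed_mg = if ("seed_mg" %in% names(d)) d$seed_mg else 10,
                    rpm = if ("rpm" %in% names(d)) d$rpm else NA_real_,
                    inhibitor_molar = if ("inhibitor_molar" %in% names(d))
                      d$inhibitor_molar else 0,
                    label = d$label, t_ca = d$t_ca_molar)
  })
}

#' Read an inhibition-series CSV
#'
#' Columns `inhibitor_molar`, `rate`; the row with `inhibitor_molar = 0`
#' carries the control rate \eqn{R_0}. Lines starting with `#` are
#' comments.
#'
#' @param path CSV file path.
#' @return data.frame with columns `conc`, `rate` and attribute
#'   `rate_control`.
#' @export
read_inhibition_csv <- function(path) {
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("inhibitor_molar", "rate") %in% names(df))) {
    stop("inhibition CSV must have columns inhibitor_molar, rate", call. = FALSE)
  }
  ctrl <- df$rate[df$inhibitor_molar == 0]
  if (length(ctrl) != 1) {
    stop("inhibition CSV must contain exactly one control row ",
         "(inhibitor_molar = 0)", call. = FALSE)
  }
  out <- data.frame(conc = df$inhibitor_molar[df$inhibitor_molar > 0],
                    rate = df$rate[df$inhibitor_molar > 0])
  attr(out, "rate_control") <- ctrl
  out
}

#' Read a titration-trace CSV
#'
#' Columns `time_min`, `volume_cm3`; metadata in `#`-prefixed header lines
#' of the form `# key: value` for `titrant_conc`, `seed_mg`, `ssa`, which
#' can also be supplied (or overridden) as arguments.
#'
#' @param path CSV file path.
#' @param titrant_conc,seed_mg,ssa Metadata overrides.
#' @return A [titration_trace()].
#' @export
read_trace_csv <- function(path, titrant_conc = NULL, seed_mg = NULL,
                           ssa = NULL) {
  hdr <- readLines(path, n = 20L)
  hdr <- hdr[startsWith(hdr, "#")]
  meta <- list()
  for (ln in hdr) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*([-0-9.eE+]+)", ln))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- as.numeric(m[3])
  }
  pick <- function(arg, key) if (!is.null(arg)) arg else meta[[key]]
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  titration_trace(df$time_min, df$volume_cm3,
                  titrant_conc = pick(titrant_conc, "titrant_conc"),
                  seed_mg = pick(seed_mg, "seed_mg"),
                  ssa = if (!is.null(pick(ssa, "ssa"))) pick(ssa, "ssa") else 3.73)
}

#' Read an energies CSV
#'
#' Columns `label`, `e_total_ev`, optionally `e_homo_ev`, `e_lumo_ev`,
#' `e_gap_ev` (pre-computed gaps for systems whose orbital energies are
#' not available).
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
read_energies_csv <- function(path) {
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("label", "e_total_ev") %in% names(df))) {
    stop("energies CSV must have columns label, e_total_ev", call. = FALSE)
  }
  ok <- !is.na(df$e_homo_ev) & !is.na(df$e_lumo_ev)
  if (any(ok) && any(df$e_lumo_ev[ok] < df$e_homo_ev[ok])) {
    stop("invariant violated in energies table: E_LUMO < E_HOMO", call. = FALSE)
  }
  df
}

#' Packaged reference dissolution table
#'
#' The two constant-composition dissolution series (control and
#' coffee-extract additive) at 37 C, pH 6, I = 0.15 mol dm^-3, shipped as
#' a plain-text fixture.
#'
#' @return A list of two [dissolution_run()] objects (`additive`,
#'   `control`).
#' @export
com_dissolution_table <- function() {
  read_dissolution_csv(system.file("extdata", "com_dissolution.csv",
                                   package = "comdiss"))
}

#' Packaged reference inhibition table
#'
#' Dissolution rate versus coffee-extract concentration at sigma = 0.20,
#' with the control rate attached as attribute `rate_control`.
#'
#' @return data.frame (`conc`, `rate`) with attribute `rate_control`.
#' @export
com_inhibition_table <- function() {
  read_inhibition_csv(system.file("extdata", "com_inhibition.csv",
                                  package = "comdiss"))
}

#' Packaged reference energies table
#'
#' DFT total energies (eV) and published HOMO-LUMO gaps for caffeine,
#' calcium oxalate and their complex in water.
#'
#' @return data.frame.
#' @export
com_energy_table <- function() {
  read_energies_csv(system.file("extdata", "com_energies.csv",
                                package = "comdiss"))
}
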