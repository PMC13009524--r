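# stable content hash for provenance: md5 of a version-pinned serialization
.content_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Run the full dissolution-inhibition analysis
#'
#' Composes the pipeline stages in experiment order: power rate-law fits
#' for every dissolution series (control required), percent inhibition and
#' both Langmuir analyses for the inhibition series, Gibbs free energy of
#' adsorption, and the scalar adsorption-energy arithmetic for an optional
#' energies table. The result is deterministic given its inputs and
#' serializes losslessly through [write_com_report()].
#'
#' @param runs List of [dissolution_run()] objects; one must be labelled
#'   `control_label`.
#' @param inhibition Optional data.frame (`conc`, `rate`) with attribute
#'   `rate_control`, as from [read_inhibition_csv()]; `NULL` skips the
#'   adsorption stage.
#' @param energies Optional energies data.frame (see [read_energies_csv()]);
#'   `NULL` skips the energetics stage.
#' @param constants A [com_constants()] object (temperature, water
#'   molarity, gas constant, \eqn{H_0^{1/2}}).
#' @param control_label Label identifying the control run.
#' @param complex_label,part_labels Energetics labels, passed to
#'   [energetics_summary()].
#' @return An object of class `com_analysis_report`.
#' @examples
#' rep <- run_com_analysis(com_dissolution_table(), com_inhibition_table(),
#'                         com_energy_table())
#' rep$adsorption$k_ads
#' @export
run_com_analysis <- function(runs, inhibition = NULL, energies = NULL,
                             constants = com_constants(),
                             control_label = "control",
                             complex_label = "complex",
                             part_labels = c("caffeine", "caox")) {
  if (inherits(runs, "dissolution_run")) runs <- list(runs)
  labels <- vapply(runs, function(r) r$label[1], character(1))
  names(runs) <- labels
  if (!control_label %in% labels) {
    stop("no run labelled '", control_label, "': a control series is required",
         call. = FALSE)
  }
  rate_law <- lapply(runs, function(r) {
    f <- fit_rate_law(r)
    f$fit <- NULL  # keep the report serializable
    f
  })

  adsorption <- NULL
  if (!is.null(inhibition) && nrow(inhibition) > 0) {
    r0 <- attr(inhibition, "rate_control")
    if (is.null(r0)) stop("inhibition table lacks a control rate", call. = FALSE)
    kin <- langmuir_kinetic_fit(inhibition$conc, inhibition$rate, r0)
    iso <- langmuir_isotherm_fit(
      inhibition$conc, inhibition$rate, r0,
      temperature = constants$physical$temperature_K,
      water_molarity = constants$physical$water_molarity,
      gas_constant = constants$physical$gas_constant)
    adsorption <- list(
      rate_control = r0,
      table = data.frame(
        conc = inhibition$conc, rate = inhibition$rate,
        theta = surface_coverage(inhibition$rate, r0),
        pct_inhibition = percent_inhibition(r0, inhibition$rate)),
      k_l = kin$constant,
      kinetic = list(slope = kin$slope, intercept = kin$intercept,
                     r_squared = kin$r_squared),
      k_ads = iso$constant,
      isotherm = list(slope = iso$slope, intercept = iso$intercept,
                      r_squared = iso$r_squared),
      delta_g_ads_kj_mol = iso$delta_g,
      water_molarity = constants$physical$water_molarity,
      temperature_K = constants$physical$temperature_K)
  }

  energetics <- if (!is.null(energies)) {
    energetics_summary(energies, complex = complex_label, parts = part_labels)
  }

  structure(
    list(rate_law = rate_law, adsorption = adsorption,
         energetics = energetics,
         provenance = list(
           package = "comdiss",
           version = as.character(packageVersion("comdiss")),
           h0_sqrt = constants$physical$h0_sqrt,
           input_hashes = list(
             runs = .content_hash(lapply(runs, as.data.frame)),
             inhibition = if (!is.null(inhibition)) .content_hash(inhibition),
             energies = if (!is.null(energies)) .content_hash(energies)))),
    class = "com_analysis_report"
  )
}

#' @export
print.com_analysis_report <- function(x, ...) {
  cat("COM dissolution-inhibition analysis report\n")
  for (nm in names(x$rate_law)) {
    f <- x$rate_law[[nm]]
    cat(sprintf("  rate law [%s]: n = %.3f (-> %d), k = %.4g, r^2 = %.4f\n",
                nm, f$n, f$n_rounded, f$k, f$r_squared))
  }
  if (!is.null(x$adsorption)) {
    a <- x$adsorption
    cat(sprintf("  adsorption: K_L = %.4g, K_ads = %.4g dm^3 mol^-1, ",
                a$k_l, a$k_ads))
    cat(sprintf("dG = %.3f kJ/mol\n", a$delta_g_ads_kj_mol))
    cat(sprintf("  max inhibition: %.3f %% at C = %.3g mol dm^-3\n",
                max(a$table$pct_inhibition),
                a$table$conc[which.max(a$table$pct_inhibition)]))
  }
  if (!is.null(x$energetics)) {
    e <- x$energetics
    cat(sprintf("  energetics: E_ads = %.3f eV (%s)",
                e$e_ads_ev, e$classification))
    if (!is.null(e$gap_widening_ev)) {
      cat(sprintf(", gap %.3f -> %.3f eV (+%.3f)",
                  e$gap_part_ev, e$gap_complex_ev, e$gap_widening_ev))
    }
    cat("\n")
  }
  invisible(x)
}

#' Write an analysis report as deterministic JSON
#'
#' Serialization is byte-stable: fixed 15-digit float formatting, no
#' timestamps, so re-running the same analysis on the same inputs yields
#' an identical file.
#'
#' @param report A [run_com_analysis()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_com_report <- function(report, path) {
  stopifnot(inherits(report, "com_analysis_report"))
  body <- unclass(report)
  body$rate_law <- lapply(body$rate_law, function(f) f[setdiff(names(f), "fit")])
  jsonlite::write_json(body, path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' Read back a JSON analysis report
#'
#' @param path File written by [write_com_report()].
#' @return A list mirroring the report structure.
#' @export
read_com_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
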