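#' HOMO-LUMO energy gap
#'
#' \eqn{E_g = E_{LUMO} - E_{HOMO}}. A widening gap upon complex formation
#' indicates electronic stabilization and reduced reactivity.
#'
#' @param e_homo,e_lumo Orbital energies, eV.
#' @return Gap in eV (non-negative).
#' @export
energy_gap <- function(e_homo, e_lumo) {
  if (any(is.na(e_homo)) || any(is.na(e_lumo))) {
    stop("both orbital energies must be present", call. = FALSE)
  }
  if (any(e_lumo < e_homo)) {
    stop("invariant violated: E_LUMO < E_HOMO", call. = FALSE)
  }
  e_lumo - e_homo
}

#' Gap widening between two systems
#'
#' Difference of two pre-computed HOMO-LUMO gaps (after minus before),
#' e.g. isolated adsorbate versus adsorbate-crystal complex. Positive
#' values mean the interaction widens the gap.
#'
#' @param gap_before,gap_after Gaps in eV (non-negative).
#' @return eV.
#' @examples
#' gap_widening(4.656, 5.278) # +0.622 eV
#' @export
gap_widening <- function(gap_before, gap_after) {
  if (any(gap_before < 0) || any(gap_after < 0)) {
    stop("gaps must be non-negative", call. = FALSE)
  }
  gap_after - gap_before
}

#' Adsorption energy of a complex
#'
#' \eqn{E_a = E_{complex} - (E_A + E_B)} from total energies of the complex
#' and its two isolated parts. Negative values indicate favorable binding;
#' magnitudes below about 0.5 eV are conventionally classified as
#' physisorption (hydrogen bonding / van der Waals) rather than
#' chemisorption.
#'
#' @param e_complex Total energy of the complex, eV.
#' @param e_part_a,e_part_b Total energies of the isolated parts, eV
#'   (order immaterial).
#' @param physisorption_threshold Classification boundary, eV (default
#'   -0.5): values above it (i.e. weaker binding) are labelled
#'   physisorption.
#' @return eV, with attribute `classification` one of `"physisorption"`,
#'   `"chemisorption"`, `"unbound"`.
#' @examples
#' adsorption_energy(-44009.820, -15305.276, -28704.271) # -0.273 eV
#' @export
adsorption_energy <- function(e_complex, e_part_a, e_part_b,
                              physisorption_threshold = -0.5) {
  if (any(is.na(c(e_complex, e_part_a, e_part_b)))) {
    stop("all total energies must be present", call. = FALSE)
  }
  ea <- e_complex - (e_part_a + e_part_b)
  cls <- ifelse(ea >= 0, "unbound",
                ifelse(ea > physisorption_threshold,
                       "physisorption", "chemisorption"))
  structure(ea, classification = cls)
}

#' Summarize an energies table
#'
#' Applies [adsorption_energy()] and, where gaps are available (either as
#' pre-computed `e_gap_ev` or as orbital-energy pairs), [energy_gap()] and
#' [gap_widening()] to a table read by [read_energies_csv()].
#'
#' @param energies data.frame with columns `label`, `e_total_ev`, and
#'   optionally `e_homo_ev`, `e_lumo_ev`, `e_gap_ev`.
#' @param complex,parts Labels: the complex row and the two component rows.
#' @param physisorption_threshold Passed to [adsorption_energy()].
#' @return List with `e_ads_ev`, `classification`, and (when gaps exist for
#'   the first part and the complex) `gap_part_ev`, `gap_complex_ev`,
#'   `gap_widening_ev`.
#' @export
energetics_summary <- function(energies, complex = "complex",
                               parts = c("caffeine", "caox"),
                               physisorption_threshold = -0.5) {
  stopifnot(length(parts) == 2)
  row_of <- function(lab) {
    i <- match(lab, energies$label)
    if (is.na(i)) stop("label not found in energies table: ", lab, call. = FALSE)
    energies[i, ]
  }
  cx <- row_of(complex); pa <- row_of(parts[1]); pb <- row_of(parts[2])
  ea <- adsorption_energy(cx$e_total_ev, pa$e_total_ev, pb$e_total_ev,
                          physisorption_threshold)
  out <- list(e_ads_ev = as.numeric(ea),
              classification = attr(ea, "classification"))
  gap_of <- function(row) {
    if (!is.null(row$e_gap_ev) && !is.na(row$e_gap_ev)) return(row$e_gap_ev)
    if (!is.null(row$e_homo_ev) && !is.na(row$e_homo_ev) &&
        !is.na(row$e_lumo_ev)) {
      return(energy_gap(row$e_homo_ev, row$e_lumo_ev))
    }
    NA_real_
  }
  g_part <- gap_of(pa); g_cx <- gap_of(cx)
  if (!is.na(g_part) && !is.na(g_cx)) {
    out$gap_part_ev <- g_part
    out$gap_complex_ev <- g_cx
    out$gap_widening_ev <- gap_widening(g_part, g_cx)
  }
  out
}
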