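#' Load the thermodynamic and physical constants set
#'
#' Reads a YAML constants file with three blocks: `species` (name, charge),
#' `reactions` (product, reactants, logK, optional `enabled` flag) and
#' `physical` (Debye-Huckel A, water molarity, gas constant, COM solubility
#' `h0_sqrt`, BET specific surface area, temperature). The packaged default
#' carries literature association constants for the Ca/oxalate/Na/Cl system
#' at 37 C; every value can be overridden by supplying an edited copy.
#'
#' Reactions are written as formation reactions over the components
#' (Ca, Ox, Na, Cl, H); a negative stoichiometric coefficient on H denotes
#' hydrolysis (e.g. `OH` is `{H: -1}` with `logK = -pKw`). Charge must be
#' conserved across every reaction.
#'
#' @param file Path to a YAML constants file; `NULL` uses the packaged
#'   defaults.
#' @return An object of class `com_constants`: a list with elements
#'   `species` (data.frame: name, charge), `reactions` (list of reactions,
#'   disabled ones dropped), and `physical` (named list).
#' @examples
#' cc <- com_constants()
#' cc$physical$h0_sqrt
#' @export
com_constants <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "com_constants.yaml", package = "comdiss")
  }
  raw <- yaml::read_yaml(file)
  species <- do.call(rbind, lapply(raw$species, function(s) {
    data.frame(name = s$name, charge = as.integer(s$charge))
  }))
  if (any(abs(species$charge) > 3)) {
    stop("bundled species must have |charge| <= 3", call. = FALSE)
  }
  charge_of <- setNames(species$charge, species$name)
  reactions <- lapply(raw$reactions, function(r) {
    r$reactants <- unlist(r$reactants)
    if (!is.finite(r$logK)) stop("logK must be finite for ", r$product, call. = FALSE)
    z_lhs <- sum(r$reactants * charge_of[names(r$reactants)])
    if (!isTRUE(all.equal(unname(z_lhs), r$charge))) {
      stop("charge not conserved in formation of ", r$product, call. = FALSE)
    }
    r$enabled <- if (is.null(r$enabled)) TRUE else isTRUE(r$enabled)
    r
  })
  reactions <- Filter(function(r) r$enabled, reactions)
  structure(
    list(species = species, reactions = reactions, physical = raw$physical),
    class = "com_constants"
  )
}

#' @export
print.com_constants <- function(x, ...) {
  cat("COM speciation constants:", nrow(x$species), "components,",
      length(x$reactions), "active reactions\n")
  for (r in x$reactions) {
    cat(sprintf("  %-6s logK = %8.3f\n", r$product, r$logK))
  }
  cat("physical: A =", x$physical$debye_huckel_A,
      "| H0^1/2 =", x$physical$h0_sqrt, "mol dm^-3",
      "| SSA =", x$physical$ssa_m2_per_g, "m2/g\n")
  invisible(x)
}
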