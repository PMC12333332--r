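# Physical constants and the element registry.
#
# Working unit system (matches force-field convention): length Angstrom,
# energy kcal/mol, charge elementary charge e, mass Da.  SI constants are
# used only inside the Mason-Schamp conversions.

#' Physical constants used by pepccs
#'
#' @format A named list: `kb_si` Boltzmann constant (J/K), `e_si` elementary
#'   charge (C), `amu_si` atomic mass unit (kg), `kb_kcal` Boltzmann constant
#'   (kcal/mol/K), `coulomb_kcal` Coulomb constant (kcal A / (mol e^2)),
#'   `hartree_kcal` hartree in kcal/mol, `torr_pa` one Torr in Pa,
#'   `loschmidt_cm3` gas number density at 273.15 K and 760 Torr (cm^-3).
#' @export
pepccs_constants <- list(
  kb_si        = 1.380649e-23,
  e_si         = 1.602176634e-19,
  amu_si       = 1.66053906660e-27,
  kb_kcal      = 0.0019872041,
  coulomb_kcal = 332.0637,
  hartree_kcal = 627.5095,
  torr_pa      = 101325 / 760,
  loschmidt_cm3 = (101325 / (1.380649e-23 * 273.15)) * 1e-6
)

# Registered elements with atomic masses (Da).  Interaction parameters are
# keyed by element in the buffer-gas tables; an element missing from this
# registry is an error, never a silent fallback.
.element_registry <- data.frame(
  element = c("H", "C", "N", "O", "S"),
  mass    = c(1.00794, 12.011, 14.007, 15.999, 32.06),
  stringsAsFactors = FALSE
)

#' Registered chemical elements
#'
#' Returns the element registry (symbol and atomic mass in Da).  Buffer-gas
#' interaction parameters are keyed by these symbols; geometries containing
#' other symbols are rejected.
#'
#' @return A data frame with columns `element` and `mass`.
#' @export
element_registry <- function() .element_registry

element_mass <- function(element) {
  idx <- match(element, .element_registry$element)
  if (anyNA(idx)) {
    bad <- unique(element[is.na(idx)])
    stop("unknown element symbol(s): ", paste(bad, collapse = ", "),
         " (registered: ", paste(.element_registry$element, collapse = ", "),
         ")", call. = FALSE)
  }
  .element_registry$mass[idx]
}
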