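# Buffer-gas models, Mason-Schamp conversions and ion-gas pair potentials.

.gas_cache <- new.env(parent = emptyenv())

#' Buffer-gas model
#'
#' Loads the packaged drift-gas parameterization: gas mass (Da),
#' polarizability (A^3), an effective hard-sphere half-radius used by the
#' projection approximation, and per-element 12-6 Lennard-Jones parameters
#' (well depth epsilon in kcal/mol, pair minimum distance r_min in A).
#' Each gas is a single isotropic pseudo-atom; N2 is the drift gas of the
#' packaged reference data, He is provided as a light validation gas.
#'
#' @param name `"N2"` or `"He"`.
#' @return An object of class `buffer_gas` with fields `name`, `mass`,
#'   `polarizability`, `hs_radius` and `lj` (data frame keyed by element).
#' @export
buffer_gas <- function(name = c("N2", "He")) {
  name <- match.arg(name)
  if (!is.null(.gas_cache[[name]])) return(.gas_cache[[name]])
  path <- system.file("extdata", "gas_params.csv", package = "pepccs")
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  tab <- tab[tab$gas == name, ]
  stopifnot(nrow(tab) > 0, all(tab$epsilon_kcal > 0), all(tab$r_min_A > 0))
  missing <- setdiff(element_registry()$element, tab$element)
  if (length(missing))
    stop("gas table lacks parameters for element(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  gas <- structure(list(
    name = name,
    mass = tab$gas_mass[1],
    polarizability = tab$gas_polarizability[1],
    hs_radius = tab$gas_hs_radius[1],
    lj = setNames(tab[, c("element", "epsilon_kcal", "r_min_A")],
                  c("element", "epsilon", "r_min"))
  ), class = "buffer_gas")
  .gas_cache[[name]] <- gas
  gas
}

# per-atom (epsilon, r_min) vectors for a geometry in a given gas
gas_lj_params <- function(geom, gas) {
  idx <- match(geom$element, gas$lj$element)
  if (anyNA(idx))
    stop("no ", gas$name, " interaction parameters for element(s): ",
         paste(unique(geom$element[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  list(epsilon = gas$lj$epsilon[idx], r_min = gas$lj$r_min[idx])
}

#' Pair-potential parameters for one element/gas pair
#'
#' @param gas A [buffer_gas()].
#' @param element Registered element symbol.
#' @return List with `epsilon` (kcal/mol), `r_min` (A), `gas_polarizability`
#'   (A^3) and `coulomb_k`, the Coulomb constant 332.0637 kcal A/(mol e^2)
#'   that fixes the unit system.
#' @export
pair_potential_params <- function(gas, element) {
  i <- match(element, gas$lj$element)
  if (is.na(i)) stop("no parameters for element ", element, call. = FALSE)
  list(epsilon = gas$lj$epsilon[i], r_min = gas$lj$r_min[i],
       gas_polarizability = gas$polarizability,
       coulomb_k = pepccs_constants$coulomb_kcal)
}

#' Drift-tube mobility conditions
#'
#' @param temperature Drift-tube temperature (K).
#' @param pressure Drift-tube pressure (Torr).
#' @param field Electric field strength (V/cm).
#' @param drift_length Drift length (cm).
#' @param number_density Buffer-gas number density (cm^-3); derived from
#'   temperature and pressure by the ideal-gas law unless overridden.
#' @param arrival_time Ion arrival time (s), optional.
#' @return An object of class `mobility_conditions`.
#' @export
mobility_conditions <- function(temperature, pressure, field, drift_length,
                                number_density = NULL, arrival_time = NULL) {
  vals <- c(temperature, pressure, field, drift_length)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("temperature, pressure, field and drift_length must be positive",
         call. = FALSE)
  if (is.null(number_density)) {
    p_pa <- pressure * pepccs_constants$torr_pa
    number_density <- p_pa / (pepccs_constants$kb_si * temperature) * 1e-6
  } else if (number_density <= 0) {
    stop("number_density must be positive", call. = FALSE)
  }
  if (!is.null(arrival_time) && arrival_time <= 0)
    stop("arrival_time must be positive", call. = FALSE)
  structure(list(temperature = temperature, pressure = pressure,
                 field = field, drift_length = drift_length,
                 number_density = number_density,
                 arrival_time = arrival_time),
            class = "mobility_conditions")
}

#' Ion mobility from drift velocity
#'
#' Low-field mobility `K = v_d / E`.
#'
#' @param v_d Drift velocity (cm/s).
#' @param field Electric field (V/cm).
#' @return Mobility K in cm^2/(V s).
#' @export
mobility_from_drift <- function(v_d, field) {
  if (any(field <= 0)) stop("field must be positive", call. = FALSE)
  v_d / field
}

# shared coefficient of the Mason-Schamp relation: omega = coef * t_A
mason_schamp_coef <- function(cond, ion, gas) {
  if (is.null(ion$mass))
    stop("ion mass required for Mason-Schamp conversion", call. = FALSE)
  if (ion$z == 0L)
    stop("charge state z must be non-zero", call. = FALSE)
  cc <- pepccs_constants
  mi <- ion$mass * cc$amu_si
  mb <- gas$mass * cc$amu_si
  mu <- mi * mb / (mi + mb)
  n_m3 <- cond$number_density * 1e6
  K_per_tA <- (cond$drift_length / 100) / (cond$field * 100) # K = this / t_A
  coef_m2 <- 3 * abs(ion$z) * cc$e_si / (16 * n_m3) *
    sqrt(2 * pi / (mu * cc$kb_si * cond$temperature)) / K_per_tA
  coef_m2 * 1e20 # A^2 per second of arrival time
}

#' CCS from an IM-MS arrival time (Mason-Schamp)
#'
#' Low-field Mason-Schamp relation: the collision cross section follows
#' from the measured mobility `K = L / (t_A E)`, the reduced ion/gas mass
#' and the buffer-gas number density,
#' `Omega = 3 z e / (16 N) * sqrt(2 pi / (mu k_b T)) * 1/K`.
#' With `N` derived from pressure and temperature this is algebraically
#' identical to the arrival-time form written with the 760/P and T/273.15
#' standardization factors and the STP number density.
#'
#' @param cond [mobility_conditions()] with `arrival_time` set.
#' @param ion [ion_spec()] with non-zero charge state and mass.
#' @param gas [buffer_gas()].
#' @return CCS in A^2.
#' @export
ccs_from_arrival_time <- function(cond, ion, gas) {
  if (is.null(cond$arrival_time))
    stop("arrival_time not set in mobility_conditions", call. = FALSE)
  mason_schamp_coef(cond, ion, gas) * cond$arrival_time
}

#' Arrival time for a given CCS (inverse Mason-Schamp)
#'
#' @param ccs CCS in A^2 (> 0).
#' @inheritParams ccs_from_arrival_time
#' @return Arrival time in s.
#' @export
arrival_time_from_ccs <- function(ccs, cond, ion, gas) {
  if (any(ccs <= 0)) stop("ccs must be positive", call. = FALSE)
  ccs / mason_schamp_coef(cond, ion, gas)
}

#' 12-6 Lennard-Jones pair energy
#'
#' `E_vdw = epsilon * ((r_min/r)^12 - 2 (r_min/r)^6)`: minimum value
#' `-epsilon` at `r_ab = r_min`.
#'
#' @param epsilon Well depth (kcal/mol).
#' @param r_min Position of the minimum (A).
#' @param r_ab Pair distance (A), > 0.
#' @return Energy in kcal/mol.
#' @export
vdw_energy <- function(epsilon, r_min, r_ab) {
  if (any(r_ab <= 0)) stop("r_ab must be positive", call. = FALSE)
  sr6 <- (r_min / r_ab)^6
  epsilon * (sr6^2 - 2 * sr6)
}

#' Coulomb pair energy
#'
#' `E_es = 332.0637 q_a q_b / r_ab` kcal/mol for charges in e and
#' distances in A.
#'
#' @param q_a,q_b Partial charges (e).
#' @param r_ab Pair distance (A), > 0.
#' @return Energy in kcal/mol.
#' @export
coulomb_energy <- function(q_a, q_b, r_ab) {
  if (any(r_ab <= 0)) stop("r_ab must be positive", call. = FALSE)
  pepccs_constants$coulomb_kcal * q_a * q_b / r_ab
}

#' Ion-gas interaction potential at a probe position
#'
#' The intermolecular potential felt by a buffer-gas pseudo-atom at
#' `probe`: per-atom 12-6 Lennard-Jones terms summed over the ion, plus
#' the charge-induced-dipole attraction `-(alpha/2)|E|^2` where `E` is the
#' Coulomb field of the ion's partial charges at the probe.  The gradient
#' is analytic and consistent with the energy.
#'
#' @param geom A [geometry()] (charges may be all zero).
#' @param gas A [buffer_gas()].
#' @param probe Numeric 3-vector (A); must be > 0.05 A from every atom.
#' @return List with `energy` (kcal/mol) and `gradient`
#'   (kcal/mol/A 3-vector, derivative with respect to the probe).
#' @export
ion_gas_potential <- function(geom, gas, probe) {
  stopifnot(inherits(geom, "geometry"), inherits(gas, "buffer_gas"))
  probe <- as.numeric(probe)
  if (length(probe) != 3 || !all(is.finite(probe)))
    stop("probe must be a finite 3-vector", call. = FALSE)
  d <- sqrt(colSums((t(geom$xyz) - probe)^2))
  if (min(d) <= 0.05)
    stop("probe overlaps an atom (distance <= 0.05 A)", call. = FALSE)
  lj <- gas_lj_params(geom, gas)
  res <- ion_gas_potential_cpp(geom$xyz, lj$epsilon, lj$r_min, geom$charge,
                               gas$polarizability, probe)
  list(energy = res$energy, gradient = as.numeric(res$gradient))
}
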