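# CCS engines: trajectory method (the headline engine) and projection
# approximation (a cheap geometric oracle), both with Monte-Carlo
# orientational averaging and deterministic seeding.

#' Trajectory-method configuration
#'
#' Defaults mirror the production settings of trajectory-method CCS codes
#' for peptide ions: 10 averaging cycles, 20 velocity-quadrature points,
#' 500 Monte-Carlo (orientation, impact-parameter) draws per cycle and
#' velocity node, 1000 as the orientation budget, 298.0 K.
#'
#' @param n_cycles Independent averaging cycles (between-cycle scatter
#'   yields the standard error).
#' @param n_velocity_points Gauss-Legendre nodes for the thermal
#'   relative-speed quadrature.
#' @param n_mc_per_cycle Monte-Carlo (orientation, b) draws per cycle and
#'   velocity node.
#' @param n_rotations Orientation budget; bounds the number of random
#'   orientations probed during the maximum-impact-parameter search (the
#'   collision integral itself draws fresh orientations per trajectory).
#' @param temperature Buffer-gas temperature (K).
#' @param timestep_control Adaptive-step safety factor (dimensionless);
#'   steps are refined until the relative energy drift of a trajectory is
#'   at most 1e-4.
#' @param max_steps Step budget per trajectory; exceeding it flags the
#'   trajectory as orbiting (counted with deflection pi).
#' @param seed Master RNG seed; expanded into per-cycle streams so earlier
#'   cycles are unchanged when `n_cycles` grows.
#' @return An object of class `trajectory_config`.
#' @export
trajectory_config <- function(n_cycles = 10, n_velocity_points = 20,
                              n_mc_per_cycle = 500, n_rotations = 1000,
                              temperature = 298.0, timestep_control = 0.05,
                              max_steps = 30000L, seed = 1L) {
  counts <- c(n_cycles, n_velocity_points, n_mc_per_cycle, n_rotations)
  if (any(counts < 1)) stop("all counts must be >= 1", call. = FALSE)
  if (temperature <= 0) stop("temperature must be positive", call. = FALSE)
  if (timestep_control <= 0 || timestep_control > 0.5)
    stop("timestep_control must be in (0, 0.5]", call. = FALSE)
  structure(list(n_cycles = as.integer(n_cycles),
                 n_velocity_points = as.integer(n_velocity_points),
                 n_mc_per_cycle = as.integer(n_mc_per_cycle),
                 n_rotations = as.integer(n_rotations),
                 temperature = temperature,
                 timestep_control = timestep_control,
                 max_steps = as.integer(max_steps),
                 seed = as.integer(seed)),
            class = "trajectory_config")
}

ccs_result <- function(ccs, std_error, engine, config, seed, extras = list()) {
  structure(c(list(ccs = ccs, std_error = std_error, engine = engine,
                   config = config, seed = seed), extras),
            class = "ccs_result")
}

#' @export
print.ccs_result <- function(x, ...) {
  cat(sprintf("<ccs_result> %s: %.2f +/- %.2f A^2 (seed %d)\n",
              x$engine, x$ccs, x$std_error, x$seed))
  invisible(x)
}

# Gauss-Legendre nodes/weights on the reduced-speed axis gamma in
# [0.25, 4]; the weight gamma^5 exp(-gamma^2) of the Omega(1,1) average is
# folded into the integrand and normalized by the same quadrature.  The
# excluded tails carry ~1e-4 of the total weight; cutting the near-zero
# speeds avoids the capture regime (collision energy far below the LJ well
# depth) where trajectories orbit and the impact-parameter range diverges.
speed_quadrature <- function(n) {
  gl <- pracma::gaussLegendre(n, 0.25, 4)
  list(nodes = gl$x, weights = gl$w)
}

# engine core on raw parameter vectors (also used by validation code with
# synthetic interaction parameters)
tm_ccs_impl <- function(xyz, epsilon, r_min, charge, alpha, mass_mu, config) {
  quad <- speed_quadrature(config$n_velocity_points)
  tm_ccs_cpp(xyz, epsilon, r_min, charge, alpha, mass_mu,
             config$temperature, config$n_cycles, quad$nodes, quad$weights,
             config$n_mc_per_cycle, as.double(config$seed),
             config$timestep_control, config$max_steps,
             as.integer(min(16L, config$n_rotations)))
}

#' Projection-approximation CCS
#'
#' Monte-Carlo shadow area averaged over uniformly random orientations.
#' Each atom contributes a disc of collision radius `r_min(element,
#' gas)/2 + gas half-radius`; the CCS is the mean projected union area and
#' the standard error is taken over orientations.  A cheap geometric
#' reference engine: it ignores charges and long-range attraction.
#'
#' @param geom A [geometry()].
#' @param gas A [buffer_gas()].
#' @param n_orientations Random orientations.
#' @param n_shots Monte-Carlo shots per orientation.
#' @param seed RNG seed (deterministic, independent of R's RNG state).
#' @return A `ccs_result` with `engine = "PA"`.
#' @export
ccs_projection_approximation <- function(geom, gas, n_orientations = 300,
                                         n_shots = 3000, seed = 1L) {
  stopifnot(inherits(geom, "geometry"), inherits(gas, "buffer_gas"))
  if (n_orientations < 1 || n_shots < 1)
    stop("n_orientations and n_shots must be >= 1", call. = FALSE)
  lj <- gas_lj_params(geom, gas)
  radii <- lj$r_min / 2 + gas$hs_radius
  res <- pa_ccs_cpp(geom$xyz, radii, as.integer(n_orientations),
                    as.integer(n_shots), as.double(seed))
  ccs_result(res$ccs, res$std_error, engine = "PA",
             config = list(n_orientations = n_orientations,
                           n_shots = n_shots, gas = gas$name),
             seed = as.integer(seed))
}

#' Classical deflection angle of a single gas-ion collision
#'
#' Integrates the scattering trajectory of a buffer-gas pseudo-atom in the
#' frozen ion's interaction potential ([ion_gas_potential()]) from
#' asymptotic approach to asymptotic exit, with adaptive velocity-Verlet
#' stepping refined until the total energy is conserved to 1e-4 relative.
#'
#' @param geom A [geometry()].
#' @param gas A [buffer_gas()].
#' @param b Impact parameter (A), >= 0.
#' @param g Relative speed (m/s), > 0.
#' @param orientation Optional 3x3 rotation matrix applied to the geometry
#'   before shooting (the incoming direction is fixed along -z).
#' @param mass Scattering mass (Da); defaults to the ion-gas reduced mass.
#' @param control Adaptive-step safety factor.
#' @param max_steps Step budget; exceeded means orbiting (chi = pi).
#' @return List with `chi` (radians), `energy_drift` (relative),
#'   `orbiting` (logical) and `steps`.
#' @export
deflection_angle <- function(geom, gas, b, g, orientation = NULL,
                             mass = NULL, control = 0.05,
                             max_steps = 30000L) {
  stopifnot(inherits(geom, "geometry"), inherits(gas, "buffer_gas"))
  if (b < 0) stop("impact parameter must be >= 0", call. = FALSE)
  if (g <= 0) stop("relative speed must be positive", call. = FALSE)
  xyz <- sweep(geom$xyz, 2, colMeans(geom$xyz))
  if (!is.null(orientation)) {
    orientation <- as.matrix(orientation)
    stopifnot(all(dim(orientation) == c(3, 3)))
    xyz <- xyz %*% t(orientation)
  }
  lj <- gas_lj_params(geom, gas)
  if (is.null(mass)) {
    mi <- geometry_mass(geom)
    mass <- mi * gas$mass / (mi + gas$mass)
  }
  res <- deflection_angle_cpp(xyz, lj$epsilon, lj$r_min, geom$charge,
                              gas$polarizability, mass, b, g * 1e-5,
                              control, as.integer(max_steps))
  list(chi = res$chi, energy_drift = res$energy_drift,
       orbiting = res$orbiting, steps = res$steps)
}

#' Trajectory-method CCS
#'
#' Computes the temperature-averaged momentum-transfer collision integral
#' Omega(1,1): thermal relative speeds from a Maxwell-Boltzmann-weighted
#' Gauss-Legendre quadrature, uniformly random orientations, impact
#' parameters area-uniform up to a maximum found by a doubling search
#' (smallest b with |chi| < 1e-3 at the slowest quadrature speed), and the
#' momentum-transfer integrand (1 - cos chi) along classical trajectories
#' in the full Lennard-Jones plus ion-induced-dipole potential.  The
#' result is the mean over independent cycles with the between-cycle
#' standard error; fixed seeds give bit-identical results.
#'
#' @param geom A [geometry()] carrying partial charges (may be all zero).
#' @param gas A [buffer_gas()].
#' @param config A [trajectory_config()].
#' @param ion Optional [ion_spec()]; supplies the ion mass for the reduced
#'   mass (otherwise derived from the geometry's elements).
#' @return A `ccs_result` with `engine = "TM"`, between-cycle
#'   `std_error`, per-cycle values, the maximum impact parameter and the
#'   orbiting-trajectory fraction (a warning is attached above 1%).
#' @export
ccs_trajectory_method <- function(geom, gas, config = trajectory_config(),
                                  ion = NULL) {
  stopifnot(inherits(geom, "geometry"), inherits(gas, "buffer_gas"),
            inherits(config, "trajectory_config"))
  lj <- gas_lj_params(geom, gas)
  mi <- if (!is.null(ion) && !is.null(ion$mass)) ion$mass
        else geometry_mass(geom)
  mu <- mi * gas$mass / (mi + gas$mass)
  res <- tm_ccs_impl(geom$xyz, lj$epsilon, lj$r_min, geom$charge,
                     gas$polarizability, mu, config)
  extras <- list(cycle_values = as.numeric(res$cycle_values),
                 b_max = as.numeric(res$b_max),
                 orbit_fraction = res$orbit_fraction,
                 gas = gas$name)
  if (res$orbit_fraction > 0.01)
    extras$warning <- sprintf("orbiting trajectories: %.2f%%",
                              100 * res$orbit_fraction)
  ccs_result(res$ccs, res$std_error, engine = "TM", config = config,
             seed = config$seed, extras = extras)
}

#' CCS sensitivity to the partial-charge set
#'
#' Recomputes the trajectory-method CCS of one geometry under two partial
#' charge vectors with a shared seed, so the geometric Monte-Carlo
#' sampling cancels and the difference reflects the charge distributions
#' alone (the two sets must carry the same total charge).
#'
#' @param geom A [geometry()] (its own charges are ignored).
#' @param charges_a,charges_b Per-atom charge vectors (e), equal length to
#'   the atom count, equal totals within `total_tol`.
#' @param gas A [buffer_gas()].
#' @param config A [trajectory_config()].
#' @param total_tol Tolerance on the total-charge match (e).
#' @return List with `percent_change` (100 (Omega_b - Omega_a)/Omega_a),
#'   and the two `ccs_result`s.
#' @export
compare_charge_sets <- function(geom, charges_a, charges_b, gas,
                                config = trajectory_config(),
                                total_tol = 0.02) {
  n <- n_atoms(geom)
  if (length(charges_a) != n || length(charges_b) != n)
    stop("charge vectors must match the atom count", call. = FALSE)
  if (abs(sum(charges_a) - sum(charges_b)) > total_tol)
    stop(sprintf("charge sets differ in total charge (%.4f vs %.4f e)",
                 sum(charges_a), sum(charges_b)), call. = FALSE)
  ga <- geometry(geom$element, geom$xyz, charges_a, label = geom$label)
  gb <- geometry(geom$element, geom$xyz, charges_b, label = geom$label)
  ra <- ccs_trajectory_method(ga, gas, config)
  rb <- ccs_trajectory_method(gb, gas, config)
  list(percent_change = 100 * (rb$ccs - ra$ccs) / ra$ccs,
       result_a = ra, result_b = rb)
}
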