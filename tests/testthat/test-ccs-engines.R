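# Projection-approximation and trajectory-method engines.

gas_n2 <- buffer_gas("N2")
gas_he <- buffer_gas("He")

test_that("PA of a single atom recovers the circle area", {
  si <- make_toy_ion("single_atom", element = "N")
  pa <- ccs_projection_approximation(si, gas_n2, n_orientations = 150,
                                     n_shots = 4000, seed = 7)
  R <- pair_potential_params(gas_n2, "N")$r_min / 2 + gas_n2$hs_radius
  expect_lt(abs(pa$ccs - pi * R^2), 3 * pa$std_error + 1e-8)
  expect_error(ccs_projection_approximation(si, gas_n2, 0, 10), ">= 1")
})

test_that("PA shadow is a union: overlapping atoms add nothing", {
  R <- 3.0
  one <- pepccs:::pa_ccs_cpp(matrix(0, 1, 3), R, 200L, 2000L, 11)
  two <- pepccs:::pa_ccs_cpp(matrix(0, 2, 3), c(R, R), 200L, 2000L, 11)
  expect_equal(two$ccs, one$ccs) # identical shadow, identical sampling
  # nearly-overlapping pair against the analytic two-circle union
  d <- 0.5
  pair <- pepccs:::pa_ccs_cpp(rbind(c(-d / 2, 0, 0), c(d / 2, 0, 0)),
                              c(R, R), 1L, 400000L, 13)
  # projected spacing along the fixed first orientation
  P <- rbind(c(-d / 2, 0, 0), c(d / 2, 0, 0)) %*%
    t(pepccs:::pa_orientation_matrix(13))
  s <- sqrt(sum((P[1, 1:2] - P[2, 1:2])^2))
  union_area <- 2 * pi * R^2 -
    (2 * R^2 * acos(s / (2 * R)) - (s / 2) * sqrt(4 * R^2 - s^2))
  expect_lt(abs(pair$ccs - union_area) / union_area, 0.01)
})

test_that("PA of a linear triatomic matches dense grid quadrature", {
  d <- 2.0
  tri <- geometry(c("N", "C", "N"),
                  rbind(c(-d, 0, 0), c(0, 0, 0), c(d, 0, 0)))
  lj <- pepccs:::gas_lj_params(tri, gas_n2)
  radii <- lj$r_min / 2 + gas_n2$hs_radius
  # orientation average reduces to 1-D for a linear molecule: the projected
  # spacing is d sin(theta) with cos(theta) uniform on [0, 1]
  gl <- pracma::gaussLegendre(16, 0, 1)
  areas <- vapply(gl$x, function(u) {
    s <- d * sqrt(1 - u^2)
    grid_shadow_area(rbind(c(-s, 0), c(0, 0), c(s, 0)), radii, n_grid = 600)
  }, numeric(1))
  oracle <- sum(gl$w * areas)
  pa <- ccs_projection_approximation(tri, gas_n2, n_orientations = 1500,
                                     n_shots = 3000, seed = 3)
  expect_lt(abs(pa$ccs - oracle) / oracle, 0.005)
})

test_that("deflection angles match the central-force quadrature oracle", {
  si <- make_toy_ion("single_atom", element = "N")
  pp <- pair_potential_params(gas_he, "N")
  mu <- 14.007 * gas_he$mass / (14.007 + gas_he$mass)
  V <- function(r) pp$epsilon * ((pp$r_min / r)^12 - 2 * (pp$r_min / r)^6)
  g_ms <- 1200
  E <- 0.5 * mu * (g_ms * 1e-5)^2 / KCAL_AKMA
  for (b in c(1.0, 2.0, 2.8, 3.4)) {
    chi_ref <- chi_quadrature(V, b, E)
    res <- deflection_angle(si, gas_he, b = b, g = g_ms, mass = mu,
                            control = 0.015)
    expect_lt(abs(abs(chi_ref) - abs(res$chi)), 1e-3)
    expect_lt(res$energy_drift, 1e-4)
  }
})

test_that("head-on collisions backscatter and distant ones pass straight", {
  si <- make_toy_ion("single_atom", element = "N")
  head_on <- deflection_angle(si, gas_he, b = 0, g = 1000)
  expect_lt(abs(head_on$chi - pi), 1e-3)
  far <- deflection_angle(si, gas_he, b = 30, g = 1000)
  expect_lt(abs(far$chi), 1e-3)
  expect_error(deflection_angle(si, gas_he, b = -1, g = 100), ">= 0")
  expect_error(deflection_angle(si, gas_he, b = 1, g = 0), "positive")
})

test_that("TM results are bit-identical for a fixed seed and translation
           invariant after recentring", {
  cfg <- trajectory_config(n_cycles = 4, n_velocity_points = 8,
                           n_mc_per_cycle = 120, seed = 21)
  dim0 <- make_toy_ion("rigid_dimer", element = "N", separation = 3)
  r1 <- ccs_trajectory_method(dim0, gas_n2, cfg)
  r2 <- ccs_trajectory_method(dim0, gas_n2, cfg)
  expect_identical(r1$ccs, r2$ccs)
  expect_identical(r1$cycle_values, r2$cycle_values)
  shifted <- geometry(dim0$element, dim0$xyz +
                        matrix(c(5, -3, 11), 2, 3, byrow = TRUE),
                      dim0$charge)
  r3 <- ccs_trajectory_method(shifted, gas_n2, cfg)
  expect_identical(r1$ccs, r3$ccs)
})

test_that("TM CCS is rotation invariant within Monte-Carlo error", {
  cfg <- trajectory_config(n_cycles = 6, n_velocity_points = 10,
                           n_mc_per_cycle = 250, seed = 22)
  dim0 <- make_toy_ion("rigid_dimer", element = "N", separation = 3)
  th <- 0.9
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rot <- geometry(dim0$element, t(R %*% t(dim0$xyz)), dim0$charge)
  r1 <- ccs_trajectory_method(dim0, gas_n2, cfg)
  r2 <- ccs_trajectory_method(rot, gas_n2, cfg)
  expect_lt(abs(r1$ccs - r2$ccs),
            3 * sqrt(r1$std_error^2 + r2$std_error^2))
})

test_that("TM exceeds the geometric shadow for attractive charged systems", {
  cfg <- trajectory_config(n_cycles = 6, n_velocity_points = 10,
                           n_mc_per_cycle = 200, seed = 5)
  fixtures <- list(
    make_toy_ion("charged_dipole_probe", separation = 6, delta = 0.4,
                 net = 1),
    build_polyglycine(3))
  for (fx in fixtures) {
    tm <- ccs_trajectory_method(fx, gas_n2, cfg)
    pa <- ccs_projection_approximation(fx, gas_n2, 200, 2000, seed = 5)
    expect_gt(tm$ccs, pa$ccs)
  }
})

test_that("CCS grows monotonically when all r_min are inflated", {
  cfg <- trajectory_config(n_cycles = 4, n_velocity_points = 8,
                           n_mc_per_cycle = 150, seed = 9)
  mu <- 14 * 28.0134 / (14 + 28.0134)
  ccs <- vapply(c(3.0, 3.6, 4.2), function(rm)
    pepccs:::tm_ccs_impl(matrix(0, 1, 3), 0.08, rm, 0, 0, mu, cfg)$ccs,
    numeric(1))
  expect_true(all(diff(ccs) > 0))
})

test_that("between-cycle standard error scales like 1/sqrt(n_cycles)", {
  mu <- 14 * 4.0026 / (14 + 4.0026)
  ns <- c(4, 8, 16, 32, 64)
  # the sd estimator is biased low for few cycles; divide out the
  # standard c4(n) small-sample factor before regressing
  c4 <- function(n) sqrt(2 / (n - 1)) * gamma(n / 2) / gamma((n - 1) / 2)
  mean_se <- vapply(ns, function(nc) {
    ses <- vapply(1:16, function(s) {
      cfg <- trajectory_config(n_cycles = nc, n_velocity_points = 6,
                               n_mc_per_cycle = 40, seed = 100 + s)
      pepccs:::tm_ccs_impl(matrix(0, 1, 3), 0.031, 3.4, 0, 0, mu,
                           cfg)$std_error
    }, numeric(1))
    mean(ses) / c4(nc)
  }, numeric(1))
  slope <- coef(lm(log(mean_se) ~ log(ns)))[[2]]
  expect_gt(slope, -0.6)
  expect_lt(slope, -0.4)
})

test_that("charge-set comparison isolates the charge contribution", {
  cfg <- trajectory_config(n_cycles = 4, n_velocity_points = 8,
                           n_mc_per_cycle = 150, seed = 31)
  dimer <- make_toy_ion("rigid_dimer", element = "N", separation = 8)
  q0 <- c(0, 0)
  # identical charge sets: exactly zero change (shared seed)
  expect_identical(
    compare_charge_sets(dimer, q0, q0, gas_n2, cfg)$percent_change, 0)
  # increasing dipole separation: CCS nondecreasing via induced dipole
  ccs_d <- vapply(c(0, 0.25, 0.5), function(d) {
    gq <- geometry(dimer$element, dimer$xyz, c(d, -d))
    ccs_trajectory_method(gq, gas_n2, cfg)$ccs
  }, numeric(1))
  expect_true(all(diff(ccs_d) >= 0))
  # a +1/-1 swap at equal total changes the CCS
  res <- compare_charge_sets(dimer, q0, c(1, -1), gas_n2, cfg)
  expect_gt(abs(res$percent_change), 0)
  expect_error(compare_charge_sets(dimer, 0, q0, gas_n2, cfg), "atom count")
  expect_error(compare_charge_sets(dimer, q0, c(0.5, 0.4), gas_n2, cfg),
               "total charge")
})
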