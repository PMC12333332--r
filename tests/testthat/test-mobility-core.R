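# Mason-Schamp conversions, buffer-gas tables and pair potentials.

test_that("mobility from drift velocity is v_d / E", {
  expect_equal(mobility_from_drift(0, 10), 0)
  expect_equal(mobility_from_drift(100, 10), 10)
  expect_equal(mobility_from_drift(200, 20), mobility_from_drift(100, 10))
  expect_error(mobility_from_drift(100, 0), "positive")
})

test_that("arrival-time CCS matches an independent evaluation of the
           low-field relation", {
  ion <- ion_spec(1, 322.5)
  gas <- buffer_gas("N2")
  cond <- mobility_conditions(298, 4, 18, 78, arrival_time = 0.025)
  omega <- ccs_from_arrival_time(cond, ion, gas)

  # independent spreadsheet-style arithmetic: reduced mobility against the
  # STP number density, all constants written out
  kB <- 1.380649e-23; e <- 1.602176634e-19; amu <- 1.66053906660e-27
  N0 <- 101325 / (kB * 273.15)
  K <- (78 / 100) / (0.025 * 18 * 100)
  K0 <- K * (4 / 760) * (273.15 / 298)
  mu <- (322.5 * 28.0134) / (322.5 + 28.0134) * amu
  omega_ref <- 3 * e / (16 * N0) * sqrt(2 * pi / (mu * kB * 298)) / K0 * 1e20
  expect_lt(abs(omega - omega_ref) / omega_ref, 1e-9)
})

test_that("the arrival-time relation is linear in t_A and z", {
  ion <- ion_spec(1, 500); gas <- buffer_gas("N2")
  c1 <- mobility_conditions(298, 4, 18, 78, arrival_time = 0.02)
  c2 <- mobility_conditions(298, 4, 18, 78, arrival_time = 0.04)
  expect_equal(ccs_from_arrival_time(c2, ion, gas),
               2 * ccs_from_arrival_time(c1, ion, gas))
  expect_equal(ccs_from_arrival_time(c1, ion_spec(2, 500), gas),
               2 * ccs_from_arrival_time(c1, ion, gas))
})

test_that("Mason-Schamp conversions are mutually inverse and monotone", {
  gas <- buffer_gas("N2")
  set.seed(42)
  for (i in 1:100) {
    ion <- ion_spec(sample(1:3, 1), runif(1, 100, 2000))
    cond <- mobility_conditions(runif(1, 200, 400), runif(1, 1, 10),
                                runif(1, 5, 50), runif(1, 20, 200))
    omega <- runif(1, 50, 800)
    t_a <- arrival_time_from_ccs(omega, cond, ion, gas)
    cond$arrival_time <- t_a
    expect_lt(abs(ccs_from_arrival_time(cond, ion, gas) - omega) / omega,
              1e-10)
  }
  # monotone increasing, and halving N halves t_A at fixed CCS
  ion <- ion_spec(1, 322.5)
  cond <- mobility_conditions(298, 4, 18, 78)
  expect_gt(arrival_time_from_ccs(300, cond, ion, gas),
            arrival_time_from_ccs(200, cond, ion, gas))
  cond_half <- mobility_conditions(298, 4, 18, 78,
                                   number_density = cond$number_density / 2)
  expect_equal(arrival_time_from_ccs(250, cond_half, ion, gas),
               arrival_time_from_ccs(250, cond, ion, gas) / 2)
  cond$arrival_time <- NULL
  expect_error(ccs_from_arrival_time(cond, ion, gas), "arrival_time")
  expect_error(ccs_from_arrival_time(
    mobility_conditions(298, 4, 18, 78, arrival_time = 0.01),
    ion_spec(0, 100), gas), "non-zero")
})

test_that("the 12-6 form has depth -epsilon at r_min and the right shape", {
  eps <- 0.107; rmin <- 3.9
  expect_equal(vdw_energy(eps, rmin, rmin), -eps)
  expect_equal(vdw_energy(eps, rmin, rmin / 2), 3968 * eps)
  expect_lt(vdw_energy(eps, rmin, 50 * rmin), 0)       # approaches 0 from below
  expect_gt(vdw_energy(eps, rmin, 50 * rmin), -1e-8)
  # numerical minimization confirms the global minimum
  opt <- optimize(function(r) vdw_energy(eps, rmin, r), c(0.5, 20))
  expect_equal(opt$minimum, rmin, tolerance = 1e-4)
  expect_equal(opt$objective, -eps, tolerance = 1e-8)
  expect_error(vdw_energy(eps, rmin, 0), "positive")
})

test_that("Coulomb energies use the 332.0637 constant and are antisymmetric", {
  expect_equal(coulomb_energy(0, 1, 5), 0)
  expect_equal(coulomb_energy(1, 1, 332.0637), 1.0)
  expect_equal(coulomb_energy(-0.3, 0.7, 4.2),
               -coulomb_energy(0.3, 0.7, 4.2))
  expect_error(coulomb_energy(1, 1, -1), "positive")
})

test_that("registered gases expose complete positive parameter tables", {
  for (g in c("N2", "He")) {
    gas <- buffer_gas(g)
    expect_gt(gas$mass, 0)
    expect_gt(gas$polarizability, 0)
    expect_setequal(gas$lj$element, element_registry()$element)
    expect_true(all(gas$lj$epsilon > 0) && all(gas$lj$r_min > 0))
  }
  expect_equal(buffer_gas("N2")$mass, 28.0134)
  expect_equal(buffer_gas("He")$polarizability, 0.205)
})

test_that("ion-gas potential reduces to known limits", {
  gas <- buffer_gas("N2")
  # all charges zero: pure 12-6 sum
  g2 <- geometry(c("N", "O"), rbind(c(0, 0, 0), c(3, 0, 0)))
  p <- c(0, 5, 0)
  v <- ion_gas_potential(g2, gas, p)$energy
  pN <- pair_potential_params(gas, "N"); pO <- pair_potential_params(gas, "O")
  v_ref <- vdw_energy(pN$epsilon, pN$r_min, sqrt(25)) +
    vdw_energy(pO$epsilon, pO$r_min, sqrt(9 + 25))
  expect_equal(v, v_ref, tolerance = 1e-12)
  # single neutral atom probed at r_min: -epsilon
  g1 <- geometry("C", matrix(0, 1, 3))
  pC <- pair_potential_params(gas, "C")
  expect_equal(ion_gas_potential(g1, gas, c(pC$r_min, 0, 0))$energy,
               -pC$epsilon)
  expect_error(ion_gas_potential(g1, gas, c(0.01, 0, 0)), "overlap")
})

test_that("potential gradient agrees with central differences", {
  gas <- buffer_gas("N2")
  set.seed(7)
  g5 <- geometry(c("N", "O", "C", "H", "S"), matrix(rnorm(15, sd = 2), 5, 3),
                 charge = c(0.3, -0.2, 0.5, 0.2, 0.2))
  for (probe in list(c(5, 1, -2), c(-4, 3, 2), c(0.5, -5, 1))) {
    an <- ion_gas_potential(g5, gas, probe)$gradient
    h <- 1e-5
    num <- vapply(1:3, function(i) {
      pp <- probe; pm <- probe; pp[i] <- pp[i] + h; pm[i] <- pm[i] - h
      (ion_gas_potential(g5, gas, pp)$energy -
         ion_gas_potential(g5, gas, pm)$energy) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(an - num) / pmax(abs(num), 1e-6)), 1e-5)
  }
})

test_that("the potential is invariant under rigid transformations", {
  gas <- buffer_gas("N2")
  set.seed(11)
  g5 <- geometry(c("N", "O", "C", "H", "S"), matrix(rnorm(15, sd = 2), 5, 3),
                 charge = c(0.3, -0.2, 0.5, 0.2, 0.2))
  probe <- c(4, 2, -1)
  v0 <- ion_gas_potential(g5, gas, probe)$energy
  for (i in 1:5) {
    th <- runif(3, 0, 2 * pi)
    Rz <- rbind(c(cos(th[1]), -sin(th[1]), 0), c(sin(th[1]), cos(th[1]), 0),
                c(0, 0, 1))
    Rx <- rbind(c(1, 0, 0), c(0, cos(th[2]), -sin(th[2])),
                c(0, sin(th[2]), cos(th[2])))
    R <- Rz %*% Rx
    shift <- rnorm(3, sd = 5)
    gt <- geometry(g5$element, t(R %*% t(g5$xyz)) +
                     matrix(shift, 5, 3, byrow = TRUE), g5$charge)
    vt <- ion_gas_potential(gt, gas, as.numeric(R %*% probe + shift))$energy
    expect_equal(vt, v0, tolerance = 1e-9)
  }
})
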