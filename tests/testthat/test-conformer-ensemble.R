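# RMSD superposition, ensemble clustering and Boltzmann weighting.

test_that("RMSD is zero for identical and rigidly rotated geometries", {
  set.seed(3)
  g <- geometry(rep("C", 10), matrix(rnorm(30, sd = 3), 10, 3))
  expect_equal(pairwise_rmsd(g, g), 0)
  th <- c(0.7, -1.2, 2.1)
  Rz <- rbind(c(cos(th[1]), -sin(th[1]), 0), c(sin(th[1]), cos(th[1]), 0),
              c(0, 0, 1))
  Ry <- rbind(c(cos(th[2]), 0, sin(th[2])), c(0, 1, 0),
              c(-sin(th[2]), 0, cos(th[2])))
  g_rot <- geometry(g$element, t(Rz %*% Ry %*% t(g$xyz)) + 5)
  expect_lt(pairwise_rmsd(g, g_rot), 1e-8)
})

test_that("RMSD matches brute-force minimization over rotations", {
  set.seed(17)
  for (rep in 1:3) {
    A <- matrix(rnorm(12, sd = 2), 4, 3) # asymmetric 4-point configurations
    B <- matrix(rnorm(12, sd = 2), 4, 3)
    ga <- geometry(rep("C", 4), A)
    gb <- geometry(rep("C", 4), B)
    r_kabsch <- pairwise_rmsd(ga, gb)
    # independent: centred coordinates, coarse rotation sampling refined by
    # Nelder-Mead on Euler angles
    Ac <- sweep(A, 2, colMeans(A)); Bc <- sweep(B, 2, colMeans(B))
    rot <- function(th) {
      Rz <- rbind(c(cos(th[1]), -sin(th[1]), 0),
                  c(sin(th[1]), cos(th[1]), 0), c(0, 0, 1))
      Ry <- rbind(c(cos(th[2]), 0, sin(th[2])), c(0, 1, 0),
                  c(-sin(th[2]), 0, cos(th[2])))
      Rx <- rbind(c(1, 0, 0), c(0, cos(th[3]), -sin(th[3])),
                  c(0, sin(th[3]), cos(th[3])))
      Rz %*% Ry %*% Rx
    }
    obj <- function(th) sqrt(mean(rowSums((Ac %*% t(rot(th)) - Bc)^2)))
    starts <- as.matrix(expand.grid(th1 = seq(0, 2 * pi, length.out = 7),
                                    th2 = seq(0, pi, length.out = 4),
                                    th3 = seq(0, 2 * pi, length.out = 7)))
    vals <- apply(starts, 1, obj)
    best <- order(vals)[1:3]
    r_grid <- min(vapply(best, function(i)
      optim(starts[i, ], obj, method = "Nelder-Mead",
            control = list(reltol = 1e-12, maxit = 2000))$value,
      numeric(1)))
    expect_lt(abs(r_kabsch - r_grid), 1e-3)
    expect_lte(r_kabsch, r_grid + 1e-9) # Kabsch attains the minimum
  }
})

test_that("RMSD masks select atoms and reject mismatched compositions", {
  g1 <- geometry(c("N", "H", "C"), rbind(c(0, 0, 0), c(1, 0, 0), c(0, 2, 0)))
  g2 <- geometry(c("N", "H", "C"), rbind(c(0, 0, 0), c(0, 8, 0), c(0, 2, 0)))
  # heavy mask ignores the hydrogen that moved
  expect_lt(pairwise_rmsd(g1, g2, atom_mask = "heavy"), 1e-8)
  expect_gt(pairwise_rmsd(g1, g2), 1)
  g3 <- geometry(c("N", "H"), rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_error(pairwise_rmsd(g1, g3), "differ")
})

test_that("single conformer forms a single cluster with itself as centroid", {
  g <- geometry(rep("C", 5), matrix(rnorm(15, sd = 2), 5, 3))
  ens <- ensemble("one", list(conformer(g, 0)))
  cl <- cluster_ensemble(ens)
  expect_equal(cl$labels, 1L)
  expect_equal(cl$centroid_ids, 1L)
})

test_that("planted well-separated clusters are recovered with centroids in
           the right basin", {
  syn <- make_clustered_ensemble(60, 3, within_spread = 0.3,
                                 between_separation = 2.0, seed = 41)
  cl <- cluster_ensemble(syn$ensemble, seed = 1)
  expect_equal(cl$n_clusters, 3)
  expect_true(same_partition(cl$labels, syn$labels))
  if (requireNamespace("mclust", quietly = TRUE))
    expect_gte(mclust::adjustedRandIndex(cl$labels, syn$labels), 0.95)
  # each centroid superposes onto its own template basin
  D <- rmsd_matrix(syn$ensemble, atom_mask = NULL)
  for (k in cl$centroid_ids) {
    own <- mean(D[k, syn$labels == syn$labels[k]])
    other <- mean(D[k, syn$labels != syn$labels[k]])
    expect_lt(own, other / 3)
  }
  # centroid minimizes summed RMSD within its cluster
  for (i in seq_along(cl$centroid_ids)) {
    members <- which(cl$labels == cl$labels[cl$centroid_ids[i]])
    sums <- rowSums(D[members, members, drop = FALSE])
    expect_equal(members[which.min(sums)], cl$centroid_ids[i])
  }
})

test_that("clustering is invariant under conformer permutation", {
  syn <- make_clustered_ensemble(40, 4, within_spread = 0.25,
                                 between_separation = 2.5, seed = 8)
  cl1 <- cluster_ensemble(syn$ensemble, seed = 2)
  set.seed(99)
  perm <- sample(40)
  ens_p <- ensemble("perm", syn$ensemble$conformers[perm])
  cl2 <- cluster_ensemble(ens_p, seed = 2)
  expect_true(same_partition(cl1$labels[perm], cl2$labels))
})

test_that("threshold/medoid fallback mode clusters by RMSD height", {
  syn <- make_clustered_ensemble(30, 3, within_spread = 0.2,
                                 between_separation = 3.0, seed = 12)
  cl <- cluster_ensemble(syn$ensemble, method = "threshold", threshold = 1.0)
  expect_equal(cl$n_clusters, 3)
  expect_true(same_partition(cl$labels, syn$labels))
  expect_error(cluster_ensemble(syn$ensemble, method = "threshold"),
               "threshold")
})

test_that("Boltzmann weights follow the inclusive window and exp(-dE/kT)", {
  # boundary: 3.0 kept (inclusive), 3.1 excluded
  bw <- boltzmann_weights(c(0, 2.9, 3.1), window = 3)
  expect_equal(bw$kept_ids, c(1L, 2L))
  bw2 <- boltzmann_weights(c(0, 3.0, 3.1), window = 3)
  expect_equal(bw2$kept_ids, c(1L, 2L))
  # equal energies: uniform weights
  expect_equal(boltzmann_weights(c(0, 0, 0))$weights, rep(1 / 3, 3))
  # two-level hand-computed example: ratio exp(-1.364/0.59219) ~ 0.100
  bw3 <- boltzmann_weights(c(0, 1.364), temperature = 298)
  expect_equal(bw3$weights, c(0.9091, 0.0909), tolerance = 1e-3)
  expect_equal(bw3$weights[2] / bw3$weights[1],
               exp(-1.364 / (0.0019872041 * 298)), tolerance = 1e-12)
  expect_error(boltzmann_weights(numeric(0)), "empty")
})

test_that("weights always sum to one and freeze onto the minimum as T -> 0", {
  set.seed(5)
  for (i in 1:25) {
    e <- runif(sample(2:12, 1), 0, 6)
    bw <- boltzmann_weights(e, window = runif(1, 0.5, 6),
                            temperature = runif(1, 50, 600))
    expect_equal(sum(bw$weights), 1, tolerance = 1e-12)
    expect_true(all(bw$weights > 0))
    expect_true(all((e - min(e))[-bw$kept_ids] > bw$window))
  }
  e <- c(0, 0.3, 1.2)
  w_cold <- boltzmann_weights(e, temperature = 1)$weights
  expect_gt(w_cold[1], 1 - 1e-10)
})

test_that("ensemble CCS is the weighted convex combination with propagated
           error", {
  one <- boltzmann_weights(0)
  r <- ensemble_ccs(list(list(ccs = 231.4, std_error = 1.1, seed = 1L)), one)
  expect_equal(r$ccs, 231.4)
  expect_equal(r$std_error, 1.1)

  eq <- boltzmann_weights(c(0, 0))
  expect_equal(ensemble_ccs(c(200, 300), eq)$ccs, 250)

  bw <- boltzmann_weights(c(0, 1.364), temperature = 298)
  r2 <- ensemble_ccs(c(240, 260), bw)
  expect_equal(r2$ccs, 241.818, tolerance = 1e-2)
  expect_equal(r2$ccs, sum(bw$weights * c(240, 260)), tolerance = 1e-12)
  # convexity and error propagation
  r3 <- ensemble_ccs(list(list(ccs = 200, std_error = 2, seed = 1L),
                          list(ccs = 300, std_error = 4, seed = 1L)), eq)
  expect_gte(r3$ccs, 200); expect_lte(r3$ccs, 300)
  expect_equal(r3$std_error, sqrt(0.25 * 4 + 0.25 * 16))
  expect_error(ensemble_ccs(c(1, 2, 3), eq), "kept")
})
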