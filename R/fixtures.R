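# Deterministic generators for test inputs: idealized polyglycine chains,
# toy ions with known CCS behaviour, and conformer ensembles with planted
# cluster structure.  These stand in for the upstream structure-generation
# and QM stages: they are reproducible without external engines and their
# charges follow a documented toy scheme, explicitly not a Mulliken
# surrogate.

# Ideal peptide internal coordinates (A, degrees): standard values, no
# force-field minimization.
.pep_ideal <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  b_c_oxt = 1.250, b_n_h = 1.010, b_ca_h = 1.090, b_o_h = 0.970,
  a_n_ca_c = 111.0, a_ca_c_n = 116.6, a_c_n_ca = 121.9,
  a_ca_c_o = 120.5, a_ca_c_oxt = 117.0, a_c_oxt_h = 106.0,
  a_c_n_h = 119.0, a_ca_n_h = 109.5, a_n_ca_ha = 109.5,
  omega = 180.0,
  phi = c(extended = 180.0, helical = -57.0),
  psi = c(extended = 180.0, helical = -47.0)
)

# NeRF atom placement: position d bonded to c, with bond angle b-c-d and
# dihedral a-b-c-d (degrees).
place_atom <- function(a, b, c, bond, angle, dihedral) {
  th <- angle * pi / 180
  ph <- dihedral * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  c + bond * (-cos(th) * bc + sin(th) * (cos(ph) * m + sin(ph) * n))
}

#' Build an idealized polyglycine chain
#'
#' Constructs a glycine homopolymer from standard bond lengths and angles
#' with backbone dihedrals set by the requested conformation (`extended`:
#' phi = psi = 180 deg; `helical`: phi = -57, psi = -47 deg; omega always
#' trans).  Protonation adds a third hydrogen to the N-terminal amine and
#' assigns a unit formal charge smeared over the ammonium group (+0.4 on
#' N, +0.2 on each H) - a documented toy scheme, not a population
#' analysis.  The returned geometry carries the attribute `roles` with the
#' indices of the N-terminal amine nitrogen and the C-terminal C-alpha,
#' the reference points of the compactness metric.
#'
#' @param n_residues Number of glycine residues (>= 1).
#' @param conformation `"extended"` or `"helical"`.
#' @param protonated Add the N-terminal proton and the +1 charge set.
#' @return A [geometry()] with attribute `roles` (list with
#'   `n_terminal_amine` and `c_terminal_calpha` indices).
#' @export
build_polyglycine <- function(n_residues,
                              conformation = c("extended", "helical"),
                              protonated = TRUE) {
  if (n_residues < 1) stop("n_residues must be >= 1", call. = FALSE)
  conformation <- match.arg(conformation)
  p <- .pep_ideal
  phi <- p$phi[[conformation]]; psi <- p$psi[[conformation]]

  # backbone heavy atoms N, CA, C per residue
  N <- CA <- CC <- vector("list", n_residues)
  N[[1]] <- c(0, 0, 0)
  CA[[1]] <- c(p$b_n_ca, 0, 0)
  CC[[1]] <- place_atom(c(0, 1, 0), N[[1]], CA[[1]], p$b_ca_c,
                        p$a_n_ca_c, 0)
  if (n_residues > 1) {
    for (i in 2:n_residues) {
      N[[i]] <- place_atom(N[[i - 1]], CA[[i - 1]], CC[[i - 1]],
                           p$b_c_n, p$a_ca_c_n, psi)
      CA[[i]] <- place_atom(CA[[i - 1]], CC[[i - 1]], N[[i]],
                            p$b_n_ca, p$a_c_n_ca, p$omega)
      CC[[i]] <- place_atom(CC[[i - 1]], N[[i]], CA[[i]],
                            p$b_ca_c, p$a_n_ca_c, phi)
    }
  }

  el <- character(0); xyz <- NULL; role_n <- NA_integer_; role_ca <- NA_integer_
  add <- function(sym, pos) {
    el <<- c(el, sym)
    xyz <<- rbind(xyz, pos)
    length(el)
  }
  h_index <- integer(0) # N-terminal amine hydrogens (for the charge smear)
  for (i in seq_len(n_residues)) {
    ni <- add("N", N[[i]])
    if (i == 1) {
      role_n <- ni
      n_h <- if (protonated) 3L else 2L
      for (k in seq_len(n_h))
        h_index <- c(h_index, add("H", place_atom(CC[[1]], CA[[1]], N[[1]],
                                                  p$b_n_h, p$a_ca_n_h,
                                                  60 + 120 * (k - 1))))
    } else {
      add("H", place_atom(CA[[i - 1]], CC[[i - 1]], N[[i]],
                          p$b_n_h, p$a_c_n_h, 0))
    }
    cai <- add("C", CA[[i]])
    if (i == n_residues) role_ca <- cai
    add("H", place_atom(CC[[i]], N[[i]], CA[[i]], p$b_ca_h, p$a_n_ca_ha, 119))
    add("H", place_atom(CC[[i]], N[[i]], CA[[i]], p$b_ca_h, p$a_n_ca_ha, -119))
    add("C", CC[[i]])
    # carbonyl O anti to the next residue's N (or to where it would sit)
    add("O", place_atom(N[[i]], CA[[i]], CC[[i]], p$b_c_o, p$a_ca_c_o,
                        psi + 180))
  }
  oxt <- add("O", place_atom(N[[n_residues]], CA[[n_residues]],
                             CC[[n_residues]], p$b_c_oxt, p$a_ca_c_oxt, psi))
  add("H", place_atom(CA[[n_residues]], CC[[n_residues]], xyz[oxt, ],
                      p$b_o_h, p$a_c_oxt_h, 180))

  q <- numeric(length(el))
  if (protonated) {
    q[role_n] <- 0.4
    q[h_index] <- 0.2
  }
  g <- geometry(el, xyz, q,
                label = sprintf("poly-%d-glycine %s%s", n_residues,
                                conformation,
                                if (protonated) " [M+H]+" else ""))
  attr(g, "roles") <- list(n_terminal_amine = role_n,
                           c_terminal_calpha = role_ca)
  g
}

#' Toy ions with exactly known structure
#'
#' Minimal geometries used as oracle targets for the CCS engines.
#'
#' @param kind `"single_atom"` (one atom at the origin), `"rigid_dimer"`
#'   (two atoms at +/- separation/2 on the x axis) or
#'   `"charged_dipole_probe"` (a rigid dimer carrying charges
#'   `net/2 + delta` and `net/2 - delta`).
#' @param element Element symbol (all atoms).
#' @param separation Dimer separation (A).
#' @param delta Dipole half-charge (e).
#' @param net Net charge (e).
#' @return A [geometry()].
#' @export
make_toy_ion <- function(kind = c("single_atom", "rigid_dimer",
                                  "charged_dipole_probe"),
                         element = "N", separation = 8.0, delta = 0.5,
                         net = 0.0) {
  kind <- match.arg(kind)
  switch(kind,
    single_atom = geometry(element, matrix(c(0, 0, 0), 1, 3),
                           net, label = "single_atom"),
    rigid_dimer = geometry(rep(element, 2),
                           rbind(c(-separation / 2, 0, 0),
                                 c(separation / 2, 0, 0)),
                           c(net / 2, net / 2), label = "rigid_dimer"),
    charged_dipole_probe = geometry(rep(element, 2),
                                    rbind(c(-separation / 2, 0, 0),
                                          c(separation / 2, 0, 0)),
                                    c(net / 2 + delta, net / 2 - delta),
                                    label = "charged_dipole_probe"))
}

# random compact chain used as a cluster template (step 1.5 A, soft
# self-avoidance at 1.0 A)
random_chain <- function(n_atoms) {
  xyz <- matrix(0, n_atoms, 3)
  for (k in 2:n_atoms) {
    for (try in 1:200) {
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      cand <- xyz[k - 1, ] + 1.5 * u
      d <- sqrt(colSums((t(xyz[seq_len(k - 1), , drop = FALSE]) - cand)^2))
      if (min(d) > 1.0) break
    }
    xyz[k, ] <- cand
  }
  xyz
}

#' Synthetic conformer ensemble with planted cluster structure
#'
#' Generates `n_clusters` template chains whose mutual minimum RMSD is at
#' least `between_separation`, then draws conformers around them with an
#' isotropic coordinate jitter calibrated so the expected within-cluster
#' pairwise RMSD (after superposition) is `within_spread`.  Energies are
#' either independent draws on the 0-6 kcal/mol range (`uniform`) or a per-cluster
#' basin offset drawn on 0-6 kcal/mol plus intra-cluster noise (`basin`).  Ground-truth
#' labels are returned for recovery tests.
#'
#' @param n_conformers Total conformers.
#' @param n_clusters Planted clusters (<= n_conformers).
#' @param within_spread Target within-cluster RMSD (A).
#' @param between_separation Minimum template-template RMSD (A), > 0.
#' @param energy_model `"uniform"` or `"basin"`.
#' @param seed RNG seed (generation is deterministic given the seed).
#' @param n_atoms Atoms per conformer (pseudo-atoms, element C).
#' @param peptide_id Ensemble identifier.
#' @return List with `ensemble` (an [ensemble()]) and `labels` (planted
#'   cluster id per conformer).
#' @export
make_clustered_ensemble <- function(n_conformers, n_clusters,
                                    within_spread = 0.3,
                                    between_separation = 2.0,
                                    energy_model = c("uniform", "basin"),
                                    seed = 1L, n_atoms = 30,
                                    peptide_id = "synthetic") {
  energy_model <- match.arg(energy_model)
  if (between_separation <= 0)
    stop("between_separation must be positive", call. = FALSE)
  if (n_clusters > n_conformers)
    stop("n_clusters must be <= n_conformers", call. = FALSE)
  with_local_seed(seed, {
    templates <- NULL
    for (attempt in 1:50) {
      templates <- lapply(seq_len(n_clusters), function(i) random_chain(n_atoms))
      ok <- TRUE
      if (n_clusters > 1) {
        for (i in seq_len(n_clusters - 1))
          for (j in (i + 1):n_clusters)
            if (rmsd_kabsch_cpp(templates[[i]], templates[[j]]) <
                between_separation) ok <- FALSE
      }
      if (ok) break
      templates <- NULL
    }
    if (is.null(templates))
      stop("could not place templates at the requested separation ",
           "(infeasible for this atom count)", call. = FALSE)

    # jitter sd per coordinate: E[RMSD^2] between two jittered copies is
    # 6 sigma^2, reduced by the ~7 dof removed by rigid superposition
    sigma <- within_spread / (sqrt(6) * sqrt(1 - 7 / (3 * n_atoms)))
    labels <- sort(rep_len(seq_len(n_clusters), n_conformers))
    offsets <- stats::runif(n_clusters, 0, 6)
    confs <- vector("list", n_conformers)
    energies <- numeric(n_conformers)
    for (i in seq_len(n_conformers)) {
      k <- labels[i]
      xyz <- templates[[k]] + matrix(stats::rnorm(3 * n_atoms, 0, sigma),
                                     n_atoms, 3)
      energies[i] <- switch(energy_model,
                            uniform = stats::runif(1, 0, 6),
                            basin = offsets[k] + abs(stats::rnorm(1, 0, 0.3)))
      confs[[i]] <- conformer(geometry(rep("C", n_atoms), xyz,
                                       label = sprintf("conf_%04d", i)),
                              energies[i], unit = "kcal/mol",
                              source_id = sprintf("planted_cluster_%d", k))
    }
    list(ensemble = ensemble(peptide_id, confs), labels = labels)
  })
}
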