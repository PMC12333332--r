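# Ensemble reduction (RMSD clustering with centroid extraction) and the
# energy-window Boltzmann-weighted ensemble CCS.

#' Minimum RMSD between two geometries
#'
#' Root-mean-square deviation after optimal rigid superposition (Kabsch:
#' optimal rotation plus translation, proper rotations only, no
#' reflection).
#'
#' @param a,b [geometry()] objects with identical atom count and order
#'   under the mask.
#' @param atom_mask Optional selection: logical or integer index vector,
#'   or `"heavy"` for all non-hydrogen atoms.
#' @return RMSD in A.
#' @export
pairwise_rmsd <- function(a, b, atom_mask = NULL) {
  stopifnot(inherits(a, "geometry"), inherits(b, "geometry"))
  sel_a <- resolve_mask(a, atom_mask)
  sel_b <- resolve_mask(b, atom_mask)
  if (length(sel_a) != length(sel_b))
    stop("masked atom counts differ", call. = FALSE)
  if (!identical(a$element[sel_a], b$element[sel_b]))
    stop("element composition/order differs under the mask", call. = FALSE)
  rmsd_kabsch_cpp(a$xyz[sel_a, , drop = FALSE], b$xyz[sel_b, , drop = FALSE])
}

resolve_mask <- function(geom, atom_mask) {
  n <- n_atoms(geom)
  if (is.null(atom_mask)) return(seq_len(n))
  if (identical(atom_mask, "heavy")) return(which(geom$element != "H"))
  if (is.logical(atom_mask)) {
    stopifnot(length(atom_mask) == n)
    return(which(atom_mask))
  }
  idx <- as.integer(atom_mask)
  if (any(idx < 1 | idx > n)) stop("mask index out of range", call. = FALSE)
  idx
}

#' All-pairs RMSD matrix of an ensemble
#'
#' @param ens An [ensemble()].
#' @param atom_mask Selection passed to [pairwise_rmsd()]; default
#'   `"heavy"` (hydrogen positions are basis-set sensitive).
#' @return Symmetric matrix of RMSD values (A).
#' @export
rmsd_matrix <- function(ens, atom_mask = "heavy") {
  stopifnot(inherits(ens, "ensemble"))
  g1 <- ens$conformers[[1]]$geometry
  sel <- resolve_mask(g1, atom_mask)
  if (!length(sel)) sel <- seq_len(n_atoms(g1)) # all-H edge case
  coords <- lapply(ens$conformers,
                   function(cf) cf$geometry$xyz[sel, , drop = FALSE])
  rmsd_matrix_cpp(coords)
}

#' Cluster a conformer ensemble by structural similarity
#'
#' Builds the all-pairs RMSD matrix (heavy atoms by default), converts it
#' to an affinity graph with a locally scaled Gaussian kernel (each
#' conformer's width is its 7th-nearest-neighbour RMSD, so the affinities
#' track the within-basin scale), and partitions the graph by
#' modularity-based community detection (Louvain).  Each cluster is represented by its centroid: the
#' member minimizing the summed RMSD to all members.  A plain
#' threshold/medoid mode (`method = "threshold"`: average-linkage
#' hierarchical clustering cut at `threshold` A) is provided as a
#' fallback.
#'
#' @param ens An [ensemble()] with at least one conformer.
#' @param method `"modularity"` (default) or `"threshold"`.
#' @param resolution Modularity resolution parameter (higher splits more).
#' @param threshold RMSD cut height (A) for `method = "threshold"`.
#' @param atom_mask Selection for the RMSD computation; default heavy
#'   atoms.
#' @param seed RNG seed for the community detection.
#' @return An object of class `cluster_assignment`: `labels` (integer per
#'   conformer), `centroid_ids` (one conformer index per cluster),
#'   `n_clusters`, and `rmsd_matrix_digest` (provenance checksum).
#' @export
cluster_ensemble <- function(ens, method = c("modularity", "threshold"),
                             resolution = 1.0, threshold = NULL,
                             atom_mask = "heavy", seed = 1L) {
  stopifnot(inherits(ens, "ensemble"))
  method <- match.arg(method)
  n <- length(ens$conformers)
  if (n == 1) {
    return(structure(list(labels = 1L, centroid_ids = 1L, n_clusters = 1L,
                          rmsd_matrix_digest = "single"),
                     class = "cluster_assignment"))
  }
  D <- rmsd_matrix(ens, atom_mask)
  digest <- sprintf("n=%d;sum=%.8e;max=%.8e", n, sum(D), max(D))
  if (method == "modularity") {
    # locally scaled Gaussian affinities: each conformer's kernel width is
    # its 7th-nearest-neighbour RMSD, so the graph adapts to the
    # within-cluster scale instead of the (between-cluster dominated)
    # global median
    k_local <- min(7L, n - 1L)
    sigma <- vapply(seq_len(n), function(i) {
      v <- sort(D[i, -i])
      max(v[k_local], 1e-6)
    }, numeric(1))
    W <- exp(-(D^2) / outer(sigma, sigma))
    diag(W) <- 0
    g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                             weighted = TRUE)
    labels <- with_local_seed(seed, {
      comm <- igraph::cluster_louvain(g, resolution = resolution)
      igraph::membership(comm)
    })
    labels <- as.integer(labels)
  } else {
    if (is.null(threshold))
      stop("threshold (A) required for method = 'threshold'", call. = FALSE)
    hc <- stats::hclust(stats::as.dist(D), method = "average")
    labels <- as.integer(stats::cutree(hc, h = threshold))
  }
  centroids <- vapply(sort(unique(labels)), function(k) {
    members <- which(labels == k)
    if (length(members) == 1) return(members)
    members[which.min(rowSums(D[members, members, drop = FALSE]))]
  }, integer(1))
  structure(list(labels = labels, centroid_ids = centroids,
                 n_clusters = length(centroids),
                 rmsd_matrix_digest = digest),
            class = "cluster_assignment")
}

# evaluate expr under a local R RNG seed, restoring the caller's state
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d conformers -> %d clusters\n",
              length(x$labels), x$n_clusters))
  invisible(x)
}

#' Boltzmann weights over an energy window
#'
#' Conformers with relative electronic energy within the window
#' (inclusive, `dE <= window`) of the minimum are kept and weighted by
#' `exp(-dE / (k_b T))`, normalized over the kept set.  At the default
#' 298.0 K, `k_b T = 0.59219 kcal/mol`.
#'
#' @param relative_energies Relative energies (kcal/mol); shifted so the
#'   minimum is zero.
#' @param window Energy window (kcal/mol), inclusive boundary; default 3.
#' @param temperature Weighting temperature (K).
#' @return An object of class `boltzmann_weights`: `kept_ids`, `weights`
#'   (summing to 1), `window`, `temperature`.
#' @export
boltzmann_weights <- function(relative_energies, window = 3.0,
                              temperature = 298.0) {
  if (!length(relative_energies))
    stop("empty energy list", call. = FALSE)
  if (!all(is.finite(relative_energies)))
    stop("non-finite energies", call. = FALSE)
  if (temperature <= 0) stop("temperature must be positive", call. = FALSE)
  de <- relative_energies - min(relative_energies)
  kept <- which(de <= window + 1e-12)
  kt <- pepccs_constants$kb_kcal * temperature
  w <- exp(-de[kept] / kt)
  w <- w / sum(w)
  structure(list(kept_ids = kept, weights = w, window = window,
                 temperature = temperature),
            class = "boltzmann_weights")
}

#' Boltzmann-weighted ensemble CCS
#'
#' `Omega_ens = sum w_i Omega_i` over the kept conformers, with the
#' Monte-Carlo standard errors propagated as `sqrt(sum w_i^2 se_i^2)`.
#'
#' @param conformer_ccs List of `ccs_result`s (or a numeric CCS vector),
#'   one per kept conformer, in `kept_ids` order.
#' @param weights A [boltzmann_weights()].
#' @return A `ccs_result` with `engine = "ensemble"`.
#' @export
ensemble_ccs <- function(conformer_ccs, weights) {
  stopifnot(inherits(weights, "boltzmann_weights"))
  if (is.numeric(conformer_ccs))
    conformer_ccs <- lapply(conformer_ccs, function(v)
      list(ccs = v, std_error = 0, seed = NA_integer_))
  if (length(conformer_ccs) != length(weights$weights))
    stop(sprintf("%d CCS values for %d kept conformers",
                 length(conformer_ccs), length(weights$weights)),
         call. = FALSE)
  omega <- vapply(conformer_ccs, function(r) r$ccs, numeric(1))
  se <- vapply(conformer_ccs, function(r) r$std_error, numeric(1))
  w <- weights$weights
  ccs_result(sum(w * omega), sqrt(sum(w^2 * se^2)), engine = "ensemble",
             config = list(window = weights$window,
                           temperature = weights$temperature),
             seed = conformer_ccs[[1]]$seed %||% NA_integer_,
             extras = list(member_ccs = omega, weights = w))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
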