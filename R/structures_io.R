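# Domain types for ions and conformer ensembles, plus readers/writers for
# the extended-XYZ ("xyzq") geometry format and ensemble manifests.

#' Construct a molecular geometry
#'
#' A geometry is the snapshot every CCS engine consumes: an ordered set of
#' atoms with element symbols, Cartesian coordinates (Angstrom) and partial
#' charges (elementary-charge units, e.g. Mulliken charges from a QM run).
#'
#' @param element Character vector of registered element symbols
#'   (see [element_registry()]).
#' @param xyz Numeric matrix with one row per atom and three columns (A).
#' @param charge Numeric vector of per-atom partial charges (e); defaults
#'   to zero.
#' @param label Free-text label carried on the XYZ comment line.
#' @return An object of class `geometry`.
#' @export
geometry <- function(element, xyz, charge = NULL, label = "") {
  xyz <- as.matrix(xyz)
  if (is.null(dim(xyz)) || ncol(xyz) != 3)
    stop("xyz must be an n x 3 matrix", call. = FALSE)
  storage.mode(xyz) <- "double"
  n <- nrow(xyz)
  if (n < 1) stop("a geometry needs at least one atom", call. = FALSE)
  if (length(element) != n)
    stop("element and xyz disagree on atom count", call. = FALSE)
  element_mass(element) # validates symbols
  if (!all(is.finite(xyz)))
    stop("non-finite coordinates", call. = FALSE)
  if (is.null(charge)) charge <- numeric(n)
  charge <- as.numeric(charge)
  if (length(charge) != n)
    stop("charge and xyz disagree on atom count", call. = FALSE)
  if (!all(is.finite(charge)))
    stop("non-finite charges", call. = FALSE)
  if (n > 1) {
    dmin <- min(dist(xyz))
    if (dmin < 0.1)
      stop(sprintf("degenerate geometry: atoms closer than 0.1 A (min %.4f A)",
                   dmin), call. = FALSE)
  }
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  structure(list(element = as.character(element), xyz = xyz,
                 charge = charge, label = as.character(label)[1]),
            class = "geometry")
}

#' @export
print.geometry <- function(x, ...) {
  cat(sprintf("<geometry> %d atoms (%s), net charge %+.3f e%s\n",
              n_atoms(x), paste(unique(x$element), collapse = ","),
              sum(x$charge),
              if (nzchar(x$label)) paste0("  [", x$label, "]") else ""))
  invisible(x)
}

#' Number of atoms in a geometry
#' @param g A `geometry`.
#' @return Integer atom count.
#' @export
n_atoms <- function(g) nrow(g$xyz)

#' Molecular mass of a geometry
#' @param g A `geometry`.
#' @return Mass in Da, summed over registered element masses.
#' @export
geometry_mass <- function(g) sum(element_mass(g$element))

#' Ion specification
#'
#' @param z Integer charge state (signed, non-zero for mobility
#'   conversions); `[M + H]+` ions have `z = 1`.
#' @param mass Ion mass in Da; if `NULL` it must be derivable later from a
#'   geometry via [geometry_mass()].
#' @return An object of class `ion_spec`.
#' @export
ion_spec <- function(z, mass = NULL) {
  z <- as.integer(z)
  if (length(z) != 1 || is.na(z))
    stop("z must be a single integer", call. = FALSE)
  if (!is.null(mass)) {
    mass <- as.numeric(mass)
    if (!is.finite(mass) || mass <= 0)
      stop("ion mass must be positive", call. = FALSE)
  }
  structure(list(z = z, mass = mass), class = "ion_spec")
}

#' Conformer: a geometry with an electronic energy
#'
#' @param geometry A [geometry()].
#' @param energy Electronic energy; absolute or relative.
#' @param unit Energy unit, `"kcal/mol"` or `"hartree"` (must be declared;
#'   no autodetection).
#' @param source_id Provenance string (e.g. the originating file).
#' @return An object of class `conformer` whose energy is stored in
#'   kcal/mol together with the original unit tag.
#' @export
conformer <- function(geometry, energy, unit = c("kcal/mol", "hartree"),
                      source_id = "") {
  stopifnot(inherits(geometry, "geometry"))
  unit <- match.arg(unit)
  energy <- as.numeric(energy)
  if (length(energy) != 1 || !is.finite(energy))
    stop("energy must be a single finite number", call. = FALSE)
  e_kcal <- if (unit == "hartree") energy * pepccs_constants$hartree_kcal
            else energy
  structure(list(geometry = geometry, energy = e_kcal, unit = unit,
                 source_id = as.character(source_id)[1]),
            class = "conformer")
}

#' Conformer ensemble for one peptide ion
#'
#' All conformers must share the same element composition and atom order.
#' When an ion is attached, each conformer's summed partial charges must
#' match the charge state within 0.02 e (Mulliken charges from real QM
#' logs carry rounding; a larger discrepancy signals a file mix-up).
#' Energies are re-referenced to the ensemble minimum.
#'
#' @param peptide_id Sequence string or other identifier.
#' @param conformers List of [conformer()] objects.
#' @param ion Optional [ion_spec()].
#' @param charge_tol Tolerance for the charge-sum check (e).
#' @return An object of class `ensemble`; `$relative_energy` holds energies
#'   relative to the ensemble minimum (kcal/mol).
#' @export
ensemble <- function(peptide_id, conformers, ion = NULL, charge_tol = 0.02) {
  if (!length(conformers)) stop("empty conformer list", call. = FALSE)
  if (!all(vapply(conformers, inherits, logical(1), "conformer")))
    stop("conformers must be a list of conformer objects", call. = FALSE)
  comp <- vapply(conformers,
                 function(cf) paste(cf$geometry$element, collapse = ""),
                 character(1))
  if (length(unique(comp)) != 1)
    stop("conformers differ in element composition or atom order",
         call. = FALSE)
  if (!is.null(ion)) {
    stopifnot(inherits(ion, "ion_spec"))
    qs <- vapply(conformers, function(cf) sum(cf$geometry$charge), numeric(1))
    off <- which(abs(qs - ion$z) > charge_tol)
    if (length(off))
      stop(sprintf(
        "conformer %d charge sum %.4f e does not match charge state %+d within %.2f e",
        off[1], qs[off[1]], ion$z, charge_tol), call. = FALSE)
    if (is.null(ion$mass)) ion$mass <- geometry_mass(conformers[[1]]$geometry)
  }
  e <- vapply(conformers, function(cf) cf$energy, numeric(1))
  structure(list(peptide_id = as.character(peptide_id)[1], ion = ion,
                 conformers = conformers, relative_energy = e - min(e)),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("<ensemble> %s: %d conformers, %d atoms each, dE range [0, %.3f] kcal/mol\n",
              x$peptide_id, length(x$conformers),
              n_atoms(x$conformers[[1]]$geometry),
              max(x$relative_energy)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Extended XYZ ("xyzq"): standard XYZ whose atom lines carry an optional
# fifth numeric column with the partial charge; the comment line carries the
# geometry label.  No charge-carrying XYZ standard exists, so the dialect is
# pinned here and written with fixed 6-decimal formatting.
# ---------------------------------------------------------------------------

#' Read an extended XYZ file with an optional partial-charge column
#'
#' Line 1 is the atom count, line 2 a free-text comment (kept as the
#' geometry label); each atom line is `symbol x y z [charge]`.  Missing
#' charges are read as zero.
#'
#' @param path Path to the file.
#' @return A [geometry()].
#' @export
read_xyzq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty file: ", path, call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1)
    stop(sprintf("%s line 1: malformed atom count '%s'", path, lines[1]),
         call. = FALSE)
  if (length(lines) < n + 2)
    stop(sprintf("%s: expected %d atom lines, found %d", path, n,
                 max(length(lines) - 2L, 0L)), call. = FALSE)
  label <- if (length(lines) >= 2) trimws(lines[2]) else ""
  el <- character(n); xyz <- matrix(0.0, n, 3); q <- numeric(n)
  for (i in seq_len(n)) {
    ln <- i + 2L
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(tok) < 4)
      stop(sprintf("%s line %d: expected 'symbol x y z [charge]', got '%s'",
                   path, ln, lines[ln]), call. = FALSE)
    vals <- suppressWarnings(as.numeric(tok[2:min(5, length(tok))]))
    if (anyNA(vals[1:3]))
      stop(sprintf("%s line %d: non-numeric coordinate in '%s'",
                   path, ln, lines[ln]), call. = FALSE)
    el[i] <- tok[1]
    xyz[i, ] <- vals[1:3]
    if (length(tok) >= 5) {
      if (is.na(vals[4]))
        stop(sprintf("%s line %d: non-numeric charge in '%s'",
                     path, ln, lines[ln]), call. = FALSE)
      q[i] <- vals[4]
    }
  }
  geometry(el, xyz, q, label = label)
}

#' Write a geometry as extended XYZ with a partial-charge column
#'
#' @param geom A [geometry()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_xyzq <- function(geom, path) {
  stopifnot(inherits(geom, "geometry"))
  lines <- c(sprintf("%d", n_atoms(geom)), geom$label,
             sprintf("%-2s %13.6f %13.6f %13.6f %10.6f",
                     geom$element, geom$xyz[, 1], geom$xyz[, 2],
                     geom$xyz[, 3], geom$charge))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) stop("cannot write ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Read an ensemble manifest
#'
#' A delimited text table (comma or tab, autodetected) with columns
#' `file`, `energy`, `unit` (either `hartree` or `kcal/mol`).  Geometry
#' paths are resolved relative to the manifest location.  Hartree energies
#' are converted by 627.5095 kcal/mol; the ensemble stores energies
#' relative to its minimum.
#'
#' @param path Manifest path.
#' @param peptide_id Ensemble identifier; defaults to the manifest stem.
#' @param ion Optional [ion_spec()] (enables the charge-sum invariant).
#' @return An [ensemble()].
#' @export
read_ensemble_manifest <- function(path, peptide_id = NULL, ion = NULL) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                         strip.white = TRUE)
  need <- c("file", "energy", "unit")
  if (!all(need %in% names(tab)))
    stop("manifest must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(tab$unit %in% c("hartree", "kcal/mol")))
    stop("energy unit must be 'hartree' or 'kcal/mol' (declared, never guessed)",
         call. = FALSE)
  base <- dirname(normalizePath(path))
  confs <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    f <- tab$file[i]
    if (!file.exists(f)) f <- file.path(base, tab$file[i])
    if (!file.exists(f))
      stop(sprintf("manifest row %d: geometry file not found: %s",
                   i, tab$file[i]), call. = FALSE)
    confs[[i]] <- conformer(read_xyzq(f), tab$energy[i], unit = tab$unit[i],
                            source_id = tab$file[i])
  }
  counts <- vapply(confs, function(cf) n_atoms(cf$geometry), integer(1))
  if (length(unique(counts)) != 1)
    stop("mixed atom counts across conformers: ",
         paste(unique(counts), collapse = ", "), call. = FALSE)
  if (is.null(peptide_id))
    peptide_id <- sub("\\.[^.]*$", "", basename(path))
  ensemble(peptide_id, confs, ion = ion)
}

# ---------------------------------------------------------------------------
# Packaged experimental/computed reference CCS tables (23 tryptic peptides)
# ---------------------------------------------------------------------------

.method_columns <- c(
  "B3LYP/6-31G(d)"          = "b3lyp_631gd",
  "D3(0)-B3LYP/6-31G(d)"    = "d3_0_631gd",
  "D3(BJ)-B3LYP/6-31G(d)"   = "d3_bj_631gd",
  "D3(0)-B3LYP/6-31G(d,p)"  = "d3_0_631gdp",
  "D3(BJ)-B3LYP/6-31G(d,p)" = "d3_bj_631gdp"
)

#' Registered CCS method labels
#' @return Character vector of the method names carried by the packaged
#'   reference tables.
#' @export
reference_methods <- function() names(.method_columns)

# map a registered method label to its column; arbitrary column names of
# user-supplied record tables pass through and are validated by the caller
resolve_method <- function(method, records = NULL) {
  col <- if (method %in% names(.method_columns)) .method_columns[[method]]
         else method
  if (!is.null(records) && !col %in% names(records))
    stop("unknown method '", method, "'; registered: ",
         paste(names(.method_columns), collapse = ", "),
         "; record columns: ",
         paste(setdiff(names(records), c("peptide", "exp_ccs")),
               collapse = ", "), call. = FALSE)
  col
}

#' Load the packaged reference CCS tables
#'
#' Experimental and Boltzmann-weighted computed CCS values (N2 drift gas,
#' `[M + H]+` ions) for 23 tryptic peptides of 3-14 residues.  `table1`
#' carries the 6-31G(d) columns (uncorrected B3LYP plus the D3(0) and
#' D3(BJ) dispersion variants); `table2` carries the 6-31G(d,p) dispersion
#' variants.  Values are exactly as published.
#'
#' @param which `"table1"` or `"table2"`.
#' @return A data frame of class `reference_table` with columns `peptide`,
#'   `exp_ccs` and one column per method (see [reference_methods()]).
#' @export
load_reference_table <- function(which = c("table1", "table2")) {
  which <- match.arg(which)
  path <- system.file("extdata", "reference_ccs.csv", package = "pepccs")
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  cols <- if (which == "table1")
    c("peptide", "exp_ccs", "b3lyp_631gd", "d3_0_631gd", "d3_bj_631gd")
  else
    c("peptide", "exp_ccs", "d3_0_631gdp", "d3_bj_631gdp")
  out <- tab[, cols]
  class(out) <- c("reference_table", "data.frame")
  out
}
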