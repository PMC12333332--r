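# Pipeline composition: manifest -> (optional clustering) -> per-conformer
# CCS -> energy window + Boltzmann weighting -> ensemble CCS -> optional
# evaluation against the packaged reference tables.

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE))
}

config_record <- function(config, seed, gas, window, temperature,
                          cluster_first, engine) {
  rec <- list(engine = engine, gas = gas, window = window,
              boltzmann_temperature = temperature,
              cluster_first = cluster_first, seed = seed,
              trajectory = unclass(config),
              pepccs_version = as.character(utils::packageVersion("pepccs")))
  json <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = 10)
  tf <- tempfile(fileext = ".json")
  writeLines(json, tf)
  hash <- unname(tools::md5sum(tf))
  unlink(tf)
  rec$config_hash <- hash
  rec
}

#' Run the ensemble-to-CCS pipeline
#'
#' Executes the downstream-of-QM portion of the structure-assignment
#' workflow for one conformer ensemble: load the manifest, optionally
#' reduce the ensemble to cluster centroids, compute a CCS per retained
#' conformer, apply the energy window with Boltzmann weighting, and write
#' the weighted ensemble CCS.  All randomness derives from `seed`; a
#' re-run with the same inputs and seed produces byte-identical result
#' records (timing goes to the log only).
#'
#' @param manifest Path to an ensemble manifest
#'   (see [read_ensemble_manifest()]), or an [ensemble()] object.
#' @param output_dir Directory for result artifacts; created if missing.
#'   `NULL` skips writing.
#' @param gas Buffer gas name, `"N2"` or `"He"`.
#' @param engine `"tm"` (trajectory method) or `"pa"` (projection
#'   approximation).
#' @param cluster_first Reduce the ensemble to cluster centroids before
#'   the (expensive) CCS stage.
#' @param cluster_resolution Modularity resolution for the clustering.
#' @param window Energy window (kcal/mol, inclusive).
#' @param temperature Boltzmann weighting temperature (K).
#' @param config A [trajectory_config()]; its counts control both engines
#'   (`n_mc_per_cycle` maps to PA shots, `n_cycles` to orientations x 30).
#' @param seed Master seed; overrides `config$seed`.
#' @param ion Optional [ion_spec()] forwarded to the ensemble reader.
#' @return Invisibly, a list with `ensemble_result` (a `ccs_result`),
#'   `conformer_table` (data frame), `assignment` (clustering, or NULL),
#'   `record` (the serialized provenance record) and `files`.
#' @export
run_pipeline <- function(manifest, output_dir = NULL, gas = "N2",
                         engine = c("tm", "pa"), cluster_first = TRUE,
                         cluster_resolution = 1.0, window = 3.0,
                         temperature = 298.0,
                         config = trajectory_config(), seed = NULL,
                         ion = NULL) {
  engine <- match.arg(engine)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  gas_obj <- buffer_gas(gas)
  log_lines <- character(0)
  note <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, sprintf("[%s] %s",
                                       format(Sys.time(), "%H:%M:%S"), msg))
    message(msg)
  }

  ens <- pipeline_stage("read", {
    if (inherits(manifest, "ensemble")) manifest
    else read_ensemble_manifest(manifest, ion = ion)
  })
  note("ensemble %s: %d conformers", ens$peptide_id, length(ens$conformers))

  assignment <- NULL
  keep <- seq_along(ens$conformers)
  if (cluster_first && length(ens$conformers) > 1) {
    assignment <- pipeline_stage("cluster",
      cluster_ensemble(ens, resolution = cluster_resolution,
                       seed = config$seed))
    keep <- sort(assignment$centroid_ids)
    note("clustering: %d clusters, retaining centroids", assignment$n_clusters)
  }
  rel_e <- ens$relative_energy[keep]
  rel_e <- rel_e - min(rel_e)

  t0 <- proc.time()[["elapsed"]]
  results <- pipeline_stage("ccs", lapply(seq_along(keep), function(i) {
    cf <- ens$conformers[[keep[i]]]
    sub_seed <- (config$seed + 7919L * i) %% .Machine$integer.max
    if (engine == "tm") {
      cfg <- config; cfg$seed <- as.integer(sub_seed)
      ccs_trajectory_method(cf$geometry, gas_obj, cfg, ion = ens$ion)
    } else {
      ccs_projection_approximation(cf$geometry, gas_obj,
                                   n_orientations = 30L * config$n_cycles,
                                   n_shots = config$n_mc_per_cycle,
                                   seed = sub_seed)
    }
  }))
  note("per-conformer CCS (%s) done in %.1f s", toupper(engine),
       proc.time()[["elapsed"]] - t0)

  bw <- pipeline_stage("weights",
    boltzmann_weights(rel_e, window = window, temperature = temperature))
  ens_res <- pipeline_stage("ensemble_ccs",
    ensemble_ccs(results[bw$kept_ids], bw))
  note("ensemble CCS %.2f +/- %.2f A^2 over %d kept conformers",
       ens_res$ccs, ens_res$std_error, length(bw$kept_ids))

  rec <- config_record(config, config$seed, gas, window, temperature,
                       cluster_first, engine)
  conf_tab <- data.frame(
    conformer = keep,
    source_id = vapply(ens$conformers[keep], function(cf) cf$source_id,
                       character(1)),
    rel_energy_kcal = rel_e,
    kept = seq_along(keep) %in% bw$kept_ids,
    weight = {
      w <- numeric(length(keep)); w[bw$kept_ids] <- bw$weights; w
    },
    ccs = vapply(results, function(r) r$ccs, numeric(1)),
    std_error = vapply(results, function(r) r$std_error, numeric(1)))

  record <- jsonlite::toJSON(
    c(list(peptide_id = ens$peptide_id, ccs = ens_res$ccs,
           std_error = ens_res$std_error,
           n_conformers = length(ens$conformers),
           n_retained = length(keep), n_kept = length(bw$kept_ids)),
      rec),
    auto_unbox = TRUE, digits = 10)

  files <- character(0)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    f_csv <- file.path(output_dir, "conformer_ccs.csv")
    f_json <- file.path(output_dir, "ensemble_result.jsonl")
    f_log <- file.path(output_dir, "pipeline.log")
    utils::write.csv(conf_tab, f_csv, row.names = FALSE)
    writeLines(as.character(record), f_json)
    writeLines(log_lines, f_log)
    files <- c(f_csv, f_json, f_log)
  }
  invisible(list(ensemble_result = ens_res, conformer_table = conf_tab,
                 assignment = assignment, record = as.character(record),
                 files = files))
}

#' Evaluate packaged reference tables
#'
#' Convenience front-end over [load_reference_table()],
#' [evaluate_method()] and [aggregate_best_variant()].
#'
#' @param table `"table1"` or `"table2"`.
#' @param method A method name, or `NULL` with `best_of` set.
#' @param best_of Character vector of two method names to select between
#'   per peptide.
#' @param threshold Success threshold (%), inclusive.
#' @return An `evaluation_summary`.
#' @export
evaluate_reference <- function(table = "table1", method = NULL,
                               best_of = NULL, threshold = 3.0) {
  records <- load_reference_table(table)
  if (!is.null(best_of)) {
    stopifnot(length(best_of) == 2)
    aggregate_best_variant(records, best_of[1], best_of[2],
                           threshold = threshold)
  } else if (!is.null(method)) {
    evaluate_method(records, method, threshold = threshold)
  } else {
    stop("supply method or best_of", call. = FALSE)
  }
}
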