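#' Read a run configuration
#'
#' YAML file with optional blocks `paths` (layers, occurrences, mask,
#' output), `pa`, `design`, `selection`, and a global `seed`. Missing entries
#' fall back to package defaults; the parsed config reproduces a run
#' bit-for-bit together with its inputs.
#'
#' @param path YAML file path.
#' @return A list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

cfg_pa <- function(cfg) {
  do.call(pa_config, utils::modifyList(list(seed = cfg$seed),
                                       cfg$pa %||% list()))
}

cfg_design <- function(cfg) {
  args <- utils::modifyList(list(seed = cfg$seed), cfg$design %||% list())
  if (!is.null(args$algorithms)) args$algorithms <- unlist(args$algorithms)
  do.call(modeling_design, args)
}

cfg_selection <- function(cfg) {
  args <- cfg$selection %||% list()
  if (!is.null(args$overrides)) args$overrides <- unlist(args$overrides)
  do.call(selection_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a synthetic world to disk
#'
#' Materializes a [synthetic_world()] as the same formats the pipeline reads:
#' one ESRI ASCII grid per layer, truth maps, and occurrence CSVs.
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Integer seed.
#' @param ... Passed to [synthetic_world()].
#' @return Invisibly, the manifest data.frame (file, kind).
#' @export
cmd_simulate <- function(out_dir, seed = 1L, ...) {
  world <- synthetic_world(seed = seed, ...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  grid <- world$stack$grid
  for (nm in names(world$stack$layers)) {
    f <- file.path(out_dir, paste0(nm, ".asc"))
    write_ascii_grid(world$stack$layers[[nm]], grid, f)
    manifest[[length(manifest) + 1]] <- data.frame(file = basename(f),
                                                   kind = "layer")
  }
  write_ascii_grid(world$truth$true_suitability, grid,
                   file.path(out_dir, "true_suitability.asc"))
  write_ascii_grid(world$truth$true_range, grid,
                   file.path(out_dir, "true_range.asc"))
  manifest[[length(manifest) + 1]] <- data.frame(
    file = c("true_suitability.asc", "true_range.asc"), kind = "truth")
  all_occ <- do.call(rbind, lapply(world$occ, as.data.frame))
  write_occurrences(as_occurrence_set(all_occ),
                    file.path(out_dir, "occurrences.csv"), geographic = FALSE)
  manifest[[length(manifest) + 1]] <- data.frame(file = "occurrences.csv",
                                                 kind = "occurrences")
  mf <- do.call(rbind, manifest)
  utils::write.csv(mf, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(mf)
}

#' Run the full pipeline from files
#'
#' Loads layers (ESRI ASCII grids) and an occurrence CSV, fits the ensemble
#' via [suscept()], and writes metric tables, stage summaries, the
#' threshold/delta series, ensemble maps and a JSON run report into
#' `out_dir`.
#'
#' @param layer_paths Character vector of layer files (names become layer
#'   ids).
#' @param occurrence_path CSV with columns id, x/lon, y/lat, role.
#' @param out_dir Output directory.
#' @param crs `"planar"` or `"geographic"`.
#' @param pa,design,selection Config objects (defaults used when `NULL`).
#' @param seed Integer seed.
#' @return The fitted `suscept` object, invisibly.
#' @export
cmd_run <- function(layer_paths, occurrence_path, out_dir,
                    crs = "planar", pa = NULL, design = NULL,
                    selection = NULL, seed = 1L) {
  first <- read_ascii_grid(layer_paths[1], crs = crs)
  layers <- stats::setNames(
    lapply(layer_paths, function(p) read_ascii_grid(p, crs = crs)$values),
    sub("\\.asc$", "", basename(layer_paths)))
  stack <- layer_stack(first$grid, layers)
  occ <- read_occurrences(occurrence_path)
  fit <- suscept(
    native = as_occurrence_set(occ[occ$role == "native_presence", ]),
    invasive = as_occurrence_set(occ[occ$role == "invasive_presence", ]),
    other = as_occurrence_set(occ[occ$role == "other_species", ]),
    stack = stack,
    pa = pa %||% pa_config(), design = design %||% modeling_design(),
    selection = selection %||% selection_config(), seed = seed)
  write_run_outputs(fit, out_dir)
  invisible(fit)
}

#' Write the output artifacts of a fitted model
#'
#' @param fit A `suscept` object.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_run_outputs <- function(fit, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  grid <- fit$stack$grid
  paths <- character(0)
  w <- function(p) { paths <<- c(paths, p); p }
  # per-model metrics
  met <- do.call(rbind, lapply(fit$models, function(m) {
    data.frame(id = m$id, algo = m$algo, run = m$run, pa = m$pa,
               threshold = m$threshold, sensitivity = m$eval$sensitivity,
               specificity = m$eval$specificity, tss = m$eval$tss)
  }))
  ihr <- attr(fit$stages$stage2, "ihr")
  met$ihr <- ihr[met$id]
  met$mean_pcc <- fit$series$mean_pcc[met$id]
  utils::write.csv(met, w(file.path(out_dir, "model_metrics.csv")),
                   row.names = FALSE)
  # stage report
  report <- list(
    seed = fit$seed,
    n_models = length(fit$models),
    stage_counts = lapply(fit$stages, function(s)
      as.list(s$per_algorithm_counts)),
    stage_records = lapply(fit$stages, `[[`, "record"),
    ihr_cut = attr(fit$stages$stage2, "cut"),
    selected_thresholds = fit$selected_thresholds,
    dropped_layers = fit$dropped_layers,
    rpa_total = fit$pa_plan$rpa_total,
    n_bopa = nrow(fit$pa_plan$bopa))
  jsonlite::write_json(report, w(file.path(out_dir, "run_report.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(fit$series$series))
    utils::write.csv(fit$series$series,
                     w(file.path(out_dir, "threshold_series.csv")),
                     row.names = FALSE)
  if (!is.null(fit$deltas))
    utils::write.csv(fit$deltas, w(file.path(out_dir, "delta_series.csv")),
                     row.names = FALSE)
  for (key in sprintf("%.2f", fit$selected_thresholds))
    write_ascii_grid(fit$series$opms[[key]], grid,
                     w(file.path(out_dir, paste0("opm_", key, ".asc"))))
  if (!is.null(fit$ensemble)) {
    write_ascii_grid(fit$ensemble$class_map, grid,
                     w(file.path(out_dir, "susceptibility.asc")))
    utils::write.csv(fit$ensemble$summary,
                     w(file.path(out_dir, "susceptibility_classes.csv")),
                     row.names = FALSE)
  }
  writeLines(zone_wkt(fit$pa_plan$zone),
             w(file.path(out_dir, "restriction_zone.wkt")))
  invisible(paths)
}

#' Summarize a completed run directory
#'
#' Reads the artifacts written by [cmd_run()]/[write_run_outputs()] and
#' prints per-stage model counts, the index series, selected thresholds and
#' the susceptibility class legend.
#'
#' @param run_dir Directory of a completed run.
#' @return The parsed report list, invisibly.
#' @export
cmd_report <- function(run_dir) {
  need <- file.path(run_dir, "run_report.json")
  if (!file.exists(need)) stop("incomplete run directory: missing ",
                               basename(need))
  report <- jsonlite::read_json(need, simplifyVector = TRUE)
  cat("Run report (seed", report$seed, ")\n")
  cat("Models fitted:", report$n_models, "\n")
  for (nm in names(report$stage_counts)) {
    tb <- report$stage_counts[[nm]]
    cat(" ", nm, ":", paste(sprintf("%s=%s", names(tb), unlist(tb)),
                            collapse = ", "), "\n")
  }
  cat("Selected thresholds:",
      paste(report$selected_thresholds, collapse = ", "), "\n")
  cls <- file.path(run_dir, "susceptibility_classes.csv")
  if (file.exists(cls)) {
    cat("Susceptibility classes:\n")
    print(utils::read.csv(cls), row.names = FALSE)
  } else {
    cat("No ensemble composed (empty threshold selection)\n")
  }
  invisible(report)
}
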