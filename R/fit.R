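#' Fit an invasion-susceptibility ensemble model
#'
#' Runs the full framework end to end: collinearity pruning of the layer
#' stack, fishnet deduplication of occurrences, construction of the two
#' pseudo-absence datasets (distance-filtered non-target records plus
#' constrained random points partitioned into k subsets), the
#' algorithm x run x pseudo-absence-subset model battery with
#' max-sensitivity+specificity binarization, three-stage model selection
#' (TSS cut, invasive hit-rate cut, prediction-convergence sweep), automated
#' threshold selection before marked index shifts, and the committee-style
#' ensemble products (ALMs, OPMs, classed susceptibility map).
#'
#' A fraction of the invasive presences (`invasive_holdout`) is reserved
#' before selection and never shown to stage 2, enabling unbiased recovery
#' checks on the final products.
#'
#' @param native,invasive,other `occurrence_set`s of native presences,
#'   invaded-range presences (validation only, never fitted), and non-target
#'   species records.
#' @param stack A [layer_stack()] of co-registered environmental layers.
#' @param pa A [pa_config()]; for planar grids express radii/spacing in grid
#'   units.
#' @param design A [modeling_design()].
#' @param selection A [selection_config()].
#' @param r_max Collinearity pruning threshold, default 0.75.
#' @param invasive_holdout Fraction of invasive cells held out of stage 2,
#'   default 0.25.
#' @param seed Integer seed governing every random draw.
#' @return An object of class `suscept`; see [print.suscept()],
#'   [summary.suscept()], [plot.suscept()], [predict.suscept()].
#' @export
suscept <- function(native, invasive, other, stack,
                    pa = pa_config(), design = modeling_design(),
                    selection = selection_config(),
                    r_max = 0.75, invasive_holdout = 0.25, seed = 1L) {
  cl <- match.call()
  seed <- as.integer(seed)
  grid <- stack$grid

  # 1. collinearity pruning ---------------------------------------------------
  pruned <- prune_collinear_layers(stack, r_max = r_max)

  # 2. fishnet deduplication --------------------------------------------------
  native_d <- dedup_to_cells(native, pruned)
  invasive_d <- dedup_to_cells(invasive, pruned)
  other_d <- dedup_to_cells(other, pruned)
  if (nrow(native_d) < 8) stop("too few native presence cells after cleaning")
  if (nrow(invasive_d) < 4) stop("too few invasive presence cells after cleaning")

  # invasive holdout: reserved before any selection sees it
  set.seed(seed + 11L)
  n_hold <- max(1L, round(invasive_holdout * nrow(invasive_d)))
  hold_idx <- sort(sample.int(nrow(invasive_d), n_hold))
  invasive_hold <- as_occurrence_set(invasive_d[hold_idx, , drop = FALSE],
                                     deduplicated = TRUE)
  invasive_fit <- as_occurrence_set(invasive_d[-hold_idx, , drop = FALSE],
                                    deduplicated = TRUE)

  # 3. pseudo-absence plan ----------------------------------------------------
  pa <- utils::modifyList(pa, list(seed = seed + 23L))
  class(pa) <- "pa_config"
  pa$n_replications <- design$pa_subsets
  bopa <- filter_bopa(other_d, native_d, pa, crs = grid$crs)
  zone <- build_restriction_zone(native_d, bopa, pa, crs = grid$crs)
  rpa_total <- compute_rpa_count(nrow(native_d), nrow(bopa), pa)
  random_pa <- generate_random_pa(pruned, zone, rpa_total, pa)
  subsets <- build_pa_subsets(random_pa, bopa, pa)

  # 4. model battery ----------------------------------------------------------
  design$seed <- seed + 37L
  splits <- partition_presences(native_d, design)
  pa_splits <- lapply(seq_len(design$pa_subsets), function(p) {
    n <- nrow(subsets[[p]])
    lapply(seq_len(design$n_runs), function(run) {
      set.seed(design$seed + 1000L * p + run)
      tr <- sort(sample.int(n, round(design$train_fraction * n)))
      list(train = tr, test = setdiff(seq_len(n), tr))
    })
  })
  models <- list()
  for (algo in design$algorithms) {
    for (run in seq_len(design$n_runs)) {
      for (p in seq_len(design$pa_subsets)) {
        sp <- splits[[run]]
        pp <- pa_splits[[p]][[run]]
        pa_set <- subsets[[p]]
        train_pres <- native_d[sp$train, , drop = FALSE]
        test_pres <- native_d[sp$test, , drop = FALSE]
        train_pa <- pa_set[pp$train, , drop = FALSE]
        test_pa <- pa_set[pp$test, , drop = FALSE]
        table <- assemble_training_table(train_pres, train_pa, pruned)
        mseed <- seed + 100L * match(algo, design$algorithms) +
          10L * run + p
        cont <- fit_and_predict(table, pruned, algo, seed = mseed)
        pres_sc <- extract_cell_values(cont, as_occurrence_set(test_pres, TRUE),
                                       grid)
        abs_sc <- extract_cell_values(cont, as_occurrence_set(test_pa, TRUE),
                                      grid)
        bin <- binarize_max_ss(cont, pres_sc, abs_sc)
        models[[length(models) + 1]] <- structure(list(
          id = sprintf("%s_run%d_pa%d", algo, run, p),
          algo = algo, run = run, pa = p,
          continuous_map = cont,
          threshold = bin$threshold,
          binary_map = bin$binary_map,
          eval = list(sensitivity = bin$sensitivity,
                      specificity = bin$specificity, tss = bin$tss),
          saw_invasive = FALSE), class = "suscept_model")
      }
    }
  }

  # 5. three-stage selection --------------------------------------------------
  ids <- model_ids(models)
  stage0 <- stage_result(0L, models, ids, invasive_fit, native_d, grid)
  stage1 <- stage1_filter(models, selection$tss_min, invasive_fit, native_d,
                          grid)
  s1_models <- models[ids %in% stage1$retained]
  stage2 <- stage2_filter(s1_models, invasive_fit, native_d, grid)
  s2_models <- models[ids %in% stage2$retained]
  series <- stage3_sweep(s2_models, selection, invasive_fit, native_d, grid)
  deltas <- if (!is.null(series$series) && nrow(series$series) >= 2)
    delta_series(series) else NULL
  selected <- if (!is.null(deltas)) {
    select_opm_thresholds(series, selection)
  } else if (!is.null(series$series)) {
    series$series$threshold[1]
  } else numeric(0)
  selected <- selected[sprintf("%.2f", selected) %in% names(series$opms)]

  # 6. ensemble products -------------------------------------------------------
  sel_keys <- sprintf("%.2f", sort(selected))
  ensemble <- if (length(sel_keys)) {
    compose_susceptibility_map(series$opms[sel_keys], grid,
                               native = native_d, invasive = invasive_hold)
  } else NULL
  stage_retained <- list(stage0 = ids, stage1 = stage1$retained,
                         stage2 = stage2$retained)
  algo_alms <- per_algorithm_alms(models, stage_retained)

  structure(list(call = cl, seed = seed,
                 config = list(pa = pa, design = design,
                               selection = selection, r_max = r_max,
                               invasive_holdout = invasive_holdout),
                 stack = pruned, dropped_layers = attr(pruned, "dropped"),
                 occ = list(native = native_d, invasive_fit = invasive_fit,
                            invasive_holdout = invasive_hold, other = other_d),
                 pa_plan = list(bopa = bopa, zone = zone,
                                rpa_total = rpa_total, subsets = subsets),
                 models = models,
                 stages = list(stage0 = stage0, stage1 = stage1,
                               stage2 = stage2),
                 series = series, deltas = deltas,
                 selected_thresholds = sort(selected),
                 ensemble = ensemble,
                 per_algorithm = algo_alms),
            class = "suscept")
}

#' @export
print.suscept <- function(x, ...) {
  cat("Invasion-susceptibility ensemble model\n")
  cat(sprintf("  layers: %d retained (%d dropped as collinear)\n",
              length(x$stack$layers), length(x$dropped_layers)))
  cat(sprintf("  presence cells: %d native, %d invasive (%d held out)\n",
              nrow(x$occ$native),
              nrow(x$occ$invasive_fit) + nrow(x$occ$invasive_holdout),
              nrow(x$occ$invasive_holdout)))
  cat(sprintf("  pseudo-absences: %d BOPA + %d random in %d subsets\n",
              nrow(x$pa_plan$bopa), x$pa_plan$rpa_total,
              length(x$pa_plan$subsets)))
  cat(sprintf("  models: %d fitted -> %d after TSS cut -> %d after IHR cut\n",
              length(x$models), length(x$stages$stage1$retained),
              length(x$stages$stage2$retained)))
  if (length(x$selected_thresholds))
    cat(sprintf("  selected PCC thresholds: %s\n",
                paste(sprintf("%.2f", x$selected_thresholds), collapse = ", ")))
  if (!is.null(x$ensemble))
    cat(sprintf("  susceptibility classes: 0..%d\n",
                nrow(x$ensemble$summary) - 1))
  invisible(x)
}

#' Summarize a fitted susceptibility model
#'
#' @param object A `suscept` object.
#' @param ... Unused.
#' @return A list with per-stage model counts per algorithm, the
#'   threshold-series data.frame, selected thresholds, and the per-class
#'   ensemble summary; printed as tables.
#' @export
summary.suscept <- function(object, ...) {
  counts <- lapply(object$stages, function(s) s$per_algorithm_counts)
  out <- list(stage_counts = counts,
              stage_records = lapply(object$stages, `[[`, "record"),
              series = object$series$series,
              selected_thresholds = object$selected_thresholds,
              ensemble_summary = if (!is.null(object$ensemble))
                object$ensemble$summary else NULL)
  class(out) <- "summary.suscept"
  out
}

#' @export
print.summary.suscept <- function(x, ...) {
  cat("Models per algorithm per stage:\n")
  for (nm in names(x$stage_counts)) {
    cat(" ", nm, ": ")
    tb <- x$stage_counts[[nm]]
    cat(paste(sprintf("%s=%d", names(tb), as.integer(tb)), collapse = ", "),
        "\n")
  }
  if (!is.null(x$series)) {
    cat("\nConvergence sweep (first/last rows):\n")
    n <- nrow(x$series)
    print(x$series[unique(c(1, min(2, n), n - 1, n)), ], row.names = FALSE)
  }
  cat("\nSelected thresholds:",
      paste(sprintf("%.2f", x$selected_thresholds), collapse = ", "), "\n")
  if (!is.null(x$ensemble_summary)) {
    cat("\nSusceptibility classes:\n")
    print(x$ensemble_summary, row.names = FALSE)
  }
  invisible(x)
}

#' Predict susceptibility class at point locations
#'
#' Looks up the classed susceptibility map at new coordinates.
#'
#' @param object A fitted `suscept` object with a composed ensemble.
#' @param newdata data.frame with columns `x`, `y` (or `lon`, `lat`).
#' @param ... Unused.
#' @return data.frame with `class` (integer) and `label`.
#' @export
predict.suscept <- function(object, newdata, ...) {
  if (is.null(object$ensemble)) stop("no ensemble was composed for this fit")
  if (all(c("lon", "lat") %in% names(newdata))) {
    newdata$x <- newdata$lon; newdata$y <- newdata$lat
  }
  pts <- occurrence_set(newdata$x, newdata$y, "native_presence")
  cleaned <- clean_records(pts, object$stack)
  if (nrow(cleaned) < nrow(pts))
    warning(nrow(pts) - nrow(cleaned), " point(s) off-grid or excluded dropped")
  cls <- extract_cell_values(object$ensemble$class_map, cleaned,
                             object$stack$grid)
  data.frame(x = cleaned$x, y = cleaned$y, class = cls,
             label = unname(object$ensemble$labels[as.character(cls)]))
}

#' Plot the evaluation-index series of a fitted model
#'
#' Two panels: the evaluation indices (IHR, NHR, SCR, mean TSS) against the
#' convergence threshold, and the first-difference (delta) series whose
#' marked negative IHR shifts drive threshold selection. Selected thresholds
#' are drawn as vertical dashed lines.
#'
#' @param x A `suscept` object.
#' @param ... Passed to `matplot`.
#' @export
plot.suscept <- function(x, ...) {
  s <- x$series$series
  if (is.null(s)) stop("no threshold series available")
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::matplot(s$threshold, s[, c("ihr", "nhr", "scr", "tss_mean")],
                    type = "l", lty = 1, lwd = 2,
                    col = c("firebrick", "steelblue", "darkorange", "grey40"),
                    xlab = "mean-PCC threshold", ylab = "index value", ...)
  graphics::legend("bottomleft", c("IHR", "NHR", "SCR", "mean TSS"),
                   col = c("firebrick", "steelblue", "darkorange", "grey40"),
                   lty = 1, lwd = 2, bty = "n", cex = 0.8)
  graphics::abline(v = x$selected_thresholds, lty = 2, col = "grey50")
  if (!is.null(x$deltas)) {
    graphics::matplot(x$deltas$threshold,
                      x$deltas[, c("ihr", "nhr", "scr")],
                      type = "h", lty = 1, lwd = 2,
                      col = c("firebrick", "steelblue", "darkorange"),
                      xlab = "mean-PCC threshold", ylab = "delta")
    graphics::abline(h = 0, col = "grey70")
    graphics::abline(v = x$selected_thresholds, lty = 2, col = "grey50")
  }
  invisible(x)
}
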