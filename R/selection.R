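#' Selection configuration
#'
#' Constants of the three-stage selection procedure and the
#' prediction-convergence sweep.
#'
#' @param tss_min Stage-1 TSS cut (inclusive). Default 0.8, deliberately
#'   stricter than the 0.75 often used.
#' @param pcc_grid Ascending mean-PCC threshold grid for stage 3; default
#'   0.50 to 1.00 in steps of 0.01 (51 values).
#' @param shift_c Outlier multiplier of the shift heuristic: an IHR delta is a
#'   marked shift when its magnitude exceeds `shift_c` times the median
#'   absolute nonzero delta.
#' @param shift_r Minimum length of a consecutive-decrease run flagged as a
#'   shift.
#' @param overrides Optional numeric vector of PCC thresholds to select
#'   verbatim, bypassing the heuristic.
#' @param pcc_on Compute pairwise correlations on `"binary"` (default) or
#'   `"continuous"` prediction maps.
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(tss_min = 0.8,
                             pcc_grid = seq(0.50, 1.00, by = 0.01),
                             shift_c = 3, shift_r = 3,
                             overrides = NULL,
                             pcc_on = c("binary", "continuous")) {
  stopifnot(tss_min >= -1, tss_min <= 1, all(diff(pcc_grid) > 0),
            shift_c > 0, shift_r >= 1)
  structure(list(tss_min = tss_min, pcc_grid = pcc_grid,
                 shift_c = shift_c, shift_r = as.integer(shift_r),
                 overrides = overrides, pcc_on = match.arg(pcc_on)),
            class = "selection_config")
}

model_ids <- function(models) vapply(models, `[[`, character(1), "id")

# ensemble bookkeeping for one retained set: OPM + indices
ensemble_record <- function(models, invasive, native, grid) {
  if (length(models) == 0) {
    return(list(n_models = 0L, n_algorithms = 0L, ihr = NA_real_,
                nhr = NA_real_, scr = NA_real_, tss_min = NA_real_,
                tss_mean = NA_real_, tss_max = NA_real_))
  }
  alm <- build_alm(lapply(models, `[[`, "binary_map"))
  opm <- build_opm(alm)
  tssv <- vapply(models, function(m) m$eval$tss, numeric(1))
  list(n_models = length(models),
       n_algorithms = length(unique(vapply(models, `[[`, character(1), "algo"))),
       ihr = hit_rate(opm, invasive, grid),
       nhr = hit_rate(opm, native, grid),
       scr = scr(opm),
       tss_min = min(tssv), tss_mean = mean(tssv), tss_max = max(tssv))
}

stage_result <- function(stage, models, retained_ids, invasive, native, grid) {
  retained <- models[model_ids(models) %in% retained_ids]
  algos <- vapply(retained, `[[`, character(1), "algo")
  structure(list(stage = stage,
                 retained = retained_ids,
                 per_algorithm_counts = table(algos),
                 record = ensemble_record(retained, invasive, native, grid)),
            class = "stage_result")
}

#' Stage 1: True Skill Statistic cut
#'
#' Retains every model whose holdout TSS is at or above `tss_min`. Filters
#' models that fail to discriminate presences from pseudo-absences near the
#' native range.
#'
#' @param models List of fitted models (each carrying `eval$tss`).
#' @param tss_min Inclusive cut, default 0.8.
#' @param invasive,native Validation `occurrence_set`s for the stage's
#'   ensemble bookkeeping.
#' @param grid The [grid_spec()].
#' @return A `stage_result`.
#' @export
stage1_filter <- function(models, tss_min = 0.8, invasive, native, grid) {
  tssv <- vapply(models, function(m) m$eval$tss, numeric(1))
  retained <- model_ids(models)[tssv >= tss_min]
  if (length(retained) == 0) warning("no models pass the TSS cut")
  stage_result(1L, models, retained, invasive, native, grid)
}

#' Stage 2: invasive hit-rate cut
#'
#' Computes the Invasive Hit Rate of every candidate against invaded-range
#' presences that never entered fitting, then retains models whose IHR is at
#' or above the candidate mean. Filters models that predict the native range
#' well but fail to extrapolate to invaded areas.
#'
#' @param models Candidate fitted models (stage-1 survivors).
#' @param invasive Invasive-presence `occurrence_set`; a hard error is thrown
#'   if any model saw invasive records in training.
#' @param native Native presences (bookkeeping only).
#' @param grid The [grid_spec()].
#' @return A `stage_result`; attribute `"ihr"` holds the per-candidate rates,
#'   attribute `"cut"` the mean.
#' @export
stage2_filter <- function(models, invasive, native, grid) {
  stopifnot(nrow(invasive) > 0)
  for (m in models) {
    if (isTRUE(m$saw_invasive))
      stop("contamination: model ", m$id, " was trained on invasive records")
  }
  ihr <- vapply(models, function(m) hit_rate(m$binary_map, invasive, grid),
                numeric(1))
  cut <- mean(ihr)
  retained <- model_ids(models)[ihr >= cut]
  out <- stage_result(2L, models, retained, invasive, native, grid)
  attr(out, "ihr") <- stats::setNames(ihr, model_ids(models))
  attr(out, "cut") <- cut
  out
}

#' Stage 3: prediction-convergence sweep
#'
#' Computes each survivor's mean pairwise Pearson correlation (PCC) against
#' the other survivors once, then sweeps the ascending threshold grid,
#' retaining at each value the models whose mean PCC is at or above it. Each
#' non-empty retained set yields an Overall Prediction Model (OPM) and its
#' evaluation indices. Because the per-model PCC is fixed after stage 2,
#' retained sets — and hence OPM suitable areas — are nested along the grid.
#'
#' @param models Stage-2 survivors (>= 2).
#' @param cfg A [selection_config()].
#' @param invasive,native Validation `occurrence_set`s.
#' @param grid The [grid_spec()].
#' @return An object of class `threshold_series`: list with `series` (a
#'   data.frame of per-threshold indices), `retained` (list of id vectors),
#'   `mean_pcc` (named per-model scores), and `opms` (list of OPM matrices).
#' @export
stage3_sweep <- function(models, cfg, invasive, native, grid) {
  if (length(models) < 2) {
    warning("fewer than 2 stage-2 survivors; convergence sweep degenerates")
    return(structure(list(series = NULL, retained = list(),
                          mean_pcc = numeric(0), opms = list()),
                     class = "threshold_series"))
  }
  maps <- if (cfg$pcc_on == "binary") {
    lapply(models, `[[`, "binary_map")
  } else {
    lapply(models, `[[`, "continuous_map")
  }
  pcc <- stats::setNames(mean_pairwise_pcc(maps), model_ids(models))
  rows <- list(); retained <- list(); opms <- list()
  for (t in cfg$pcc_grid) {
    ids <- names(pcc)[pcc >= t]
    if (length(ids) == 0) break
    sub <- models[model_ids(models) %in% ids]
    rec <- ensemble_record(sub, invasive, native, grid)
    rows[[length(rows) + 1]] <- data.frame(threshold = t,
                                           n_models = rec$n_models,
                                           n_algorithms = rec$n_algorithms,
                                           ihr = rec$ihr, nhr = rec$nhr,
                                           scr = rec$scr,
                                           tss_min = rec$tss_min,
                                           tss_mean = rec$tss_mean,
                                           tss_max = rec$tss_max)
    retained[[length(retained) + 1]] <- ids
    opms[[length(opms) + 1]] <- build_opm(build_alm(lapply(sub, `[[`, "binary_map")))
  }
  series <- do.call(rbind, rows)
  names(retained) <- names(opms) <- sprintf("%.2f", series$threshold)
  structure(list(series = series, retained = retained, mean_pcc = pcc,
                 opms = opms),
            class = "threshold_series")
}

#' Delta series of the evaluation indices
#'
#' First differences along the threshold grid: `delta_i = value_{i+1} -
#' value_i` for each index (IHR, NHR, SCR, min/mean/max TSS). Row i describes
#' the change incurred moving *into* threshold i+1.
#'
#' @param series A `threshold_series` (or its `series` data.frame).
#' @return data.frame with column `threshold` (the destination threshold of
#'   each step) and one delta column per index.
#' @export
delta_series <- function(series) {
  df <- if (inherits(series, "threshold_series")) series$series else series
  if (is.null(df) || nrow(df) < 2) stop("need >= 2 points in the series")
  idx <- c("ihr", "nhr", "scr", "tss_min", "tss_mean", "tss_max")
  idx <- intersect(idx, names(df))
  out <- data.frame(threshold = df$threshold[-1])
  for (nm in idx) out[[nm]] <- diff(df[[nm]])
  out
}

#' Select ensemble thresholds before marked shifts
#'
#' Codifies the visual rule used to pick Overall Prediction Models: find
#' "marked shifts" in the IHR delta series — a negative delta whose magnitude
#' exceeds `shift_c` times the median absolute delta (any strict decrease,
#' when the background is flat), or the start of
#' a run of at least `shift_r` consecutive IHR decreases — and select the
#' threshold immediately preceding each shift event. An outlier lying inside
#' a decrease run resolves to the threshold preceding the run's start. The
#' final threshold of the range is never selected. With no shifts found, the
#' median threshold of the range is returned with a warning. A manual
#' `overrides` vector in the config is honoured verbatim.
#'
#' @param series A `threshold_series`.
#' @param cfg A [selection_config()].
#' @return Ascending numeric vector of selected thresholds.
#' @export
select_opm_thresholds <- function(series, cfg = selection_config()) {
  if (!is.null(cfg$overrides)) return(sort(unique(cfg$overrides)))
  df <- if (inherits(series, "threshold_series")) series$series else series
  thr <- df$threshold
  d <- diff(df$ihr)          # d[i] = change moving from thr[i] to thr[i+1]
  scale <- stats::median(abs(d))
  neg <- d < 0
  # against a flat background (median delta 0) any strict decrease is marked
  outlier <- if (scale > 0) neg & abs(d) > cfg$shift_c * scale else neg
  # run starts: >= shift_r consecutive decreases beginning here
  runs <- rep(FALSE, length(d))
  r <- cfg$shift_r
  if (length(d) >= r) {
    for (i in seq_len(length(d) - r + 1)) {
      if (all(neg[i:(i + r - 1)]) && (i == 1 || !neg[i - 1])) runs[i] <- TRUE
    }
  }
  picks <- integer(0)
  for (i in which(outlier)) {
    j <- i
    while (j > 1 && neg[j - 1]) j <- j - 1   # walk back to the run start
    picks <- c(picks, j)
  }
  picks <- c(picks, which(runs))
  picks <- sort(unique(picks))
  sel <- thr[picks]                          # threshold preceding the event
  sel <- sel[sel < thr[length(thr)]]
  if (length(sel) == 0) {
    warning("no marked shifts found; falling back to the median threshold")
    sel <- stats::median(thr)
  }
  sel
}
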