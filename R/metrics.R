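#' True Skill Statistic from confusion counts
#'
#' `TSS = sensitivity + specificity - 1`, the threshold-dependent skill score
#' used throughout the selection pipeline in place of AUC. Ranges over
#' [-1, 1]; 0 is chance level, 1 a perfect classifier.
#'
#' @param tp,fn,tn,fp Confusion counts; both classes must be represented
#'   (`tp + fn > 0`, `tn + fp > 0`).
#' @return List with `sensitivity`, `specificity`, `tss`.
#' @export
tss_stats <- function(tp, fn, tn, fp) {
  if (tp + fn <= 0 || tn + fp <= 0)
    stop("both classes must be non-empty to compute TSS")
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  list(sensitivity = sens, specificity = spec, tss = sens + spec - 1)
}

#' Hit rate of a binary map over validation points
#'
#' The fraction of validation presence cells that fall on predicted-suitable
#' (value 1) cells: the sensitivity component of TSS computed against an
#' independent point set. Fed invaded-range presences this is the Invasive
#' Hit Rate (IHR); fed native presences, the Native Hit Rate (NHR).
#'
#' @param binary_map 0/1 matrix on the grid.
#' @param points Deduplicated validation `occurrence_set` on analyzable cells.
#' @param grid The [grid_spec()].
#' @return Hit rate in [0, 1].
#' @export
hit_rate <- function(binary_map, points, grid) {
  if (nrow(points) == 0) stop("empty validation set")
  v <- extract_cell_values(binary_map, points, grid)
  if (anyNA(v)) stop("validation point(s) on non-analyzable cells")
  mean(v == 1)
}

#' Suitable Cells Ratio
#'
#' The fraction of analyzable cells a binary map predicts suitable:
#' `ones / (ones + zeros)`. A size measure of the predicted range.
#'
#' @param binary_map 0/1 matrix; cells outside the analyzable mask must be
#'   `NA`.
#' @return Ratio in [0, 1].
#' @export
scr <- function(binary_map) {
  v <- binary_map[!is.na(binary_map)]
  if (length(v) == 0) stop("no analyzable cells in map")
  mean(v == 1)
}

#' Mean pairwise Pearson correlation between prediction maps
#'
#' The prediction-convergence score: for each model, the mean of Pearson
#' correlations between its map and every other model's map (self excluded),
#' computed across analyzable cells. On binary maps this is the phi
#' coefficient. Models whose predictions agree with the majority score high;
#' divergent models score low.
#'
#' @param maps List of >= 2 matrices on a common grid; each must be
#'   non-constant over analyzable cells.
#' @return Numeric vector, one mean correlation per map, in input order.
#' @export
mean_pairwise_pcc <- function(maps) {
  stopifnot(length(maps) >= 2)
  mask <- !is.na(maps[[1]])
  m <- vapply(maps, function(x) as.numeric(x[mask]), numeric(sum(mask)))
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stop("constant map(s), pairwise correlation undefined: model ",
         paste(which(sds == 0), collapse = ", "))
  cm <- stats::cor(m)
  (rowSums(cm) - 1) / (ncol(m) - 1)
}
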