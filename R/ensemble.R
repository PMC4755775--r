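#' Agreement Level Model (ALM)
#'
#' Cell-wise sum of co-registered binary prediction maps: a spatialized
#' frequency histogram ranging from 0 (all members agree the cell is
#' unsuitable) to the member count. The value is a level of agreement among
#' models, not a probability or suitability level.
#'
#' @param binary_maps Non-empty list of 0/1 matrices sharing one grid.
#' @return Integer-valued matrix (`NA` outside analyzable cells).
#' @export
build_alm <- function(binary_maps) {
  stopifnot(length(binary_maps) >= 1)
  dims <- dim(binary_maps[[1]])
  for (m in binary_maps)
    if (!all(dim(m) == dims)) stop("binary maps are not co-registered")
  Reduce(`+`, binary_maps)
}

#' Overall Prediction Model (OPM)
#'
#' Binary union of the member predictions: 1 wherever at least one member
#' predicted suitability (agreement level >= 1), else 0.
#'
#' @param alm Agreement map from [build_alm()].
#' @return 0/1 matrix.
#' @export
build_opm <- function(alm) (alm >= 1) * 1

#' Per-algorithm agreement maps across selection stages
#'
#' For each (algorithm, stage) pair, the ALM over that algorithm's surviving
#' models — a way to compare algorithm behaviour as selection tightens.
#' Algorithms with zero survivors at a stage are recorded as `NULL`.
#'
#' @param models Full model list.
#' @param stage_retained Named list: stage label -> character vector of
#'   retained model ids.
#' @return Nested list `[[stage]][[algorithm]]` of ALM matrices (or `NULL`).
#' @export
per_algorithm_alms <- function(models, stage_retained) {
  ids <- model_ids(models)
  algos <- unique(vapply(models, `[[`, character(1), "algo"))
  lapply(stage_retained, function(ret) {
    sub <- models[ids %in% ret]
    sub_algos <- vapply(sub, `[[`, character(1), "algo")
    out <- lapply(algos, function(a) {
      mine <- sub[sub_algos == a]
      if (length(mine) == 0) return(NULL)
      build_alm(lapply(mine, `[[`, "binary_map"))
    })
    stats::setNames(out, algos)
  })
}

#' Susceptibility class labels
#'
#' Labels for the classed susceptibility map built from K selected OPMs:
#' class 0 is "Very Low Susceptibility or Insusceptible", class 1
#' "Susceptible", class K "Susceptible at Maximum"; with K = 3 the single
#' intermediate class is "Highly Susceptible", otherwise intermediates are
#' labelled "Susceptibility level j of K".
#'
#' @param k Number of selected OPMs (>= 1).
#' @return Character vector of length k + 1, names `"0"` ... `"k"`.
#' @export
susceptibility_labels <- function(k) {
  stopifnot(k >= 1)
  lab <- character(k + 1)
  lab[1] <- "Very Low Susceptibility or Insusceptible"
  lab[k + 1] <- "Susceptible at Maximum"
  if (k >= 2) lab[2] <- "Susceptible"
  if (k >= 3) {
    mid <- 2:(k - 1)
    lab[mid + 1] <- if (k == 3) "Highly Susceptible" else
      sprintf("Susceptibility level %d of %d", mid, k)
  }
  if (k == 1) lab[2] <- "Susceptible at Maximum"
  stats::setNames(lab, as.character(0:k))
}

#' Compose the classed susceptibility map
#'
#' Cell-wise sum of the selected OPMs (ordered by ascending selection
#' threshold). With nested OPMs the classes are concentric: the top class is
#' exactly the innermost (strictest) OPM's suitable area. Reports per-class
#' cell counts, areas, and validation hit counts.
#'
#' @param selected_opms List of 0/1 matrices, ascending threshold order;
#'   nesting is verified and a warning raised if violated (possible under
#'   manual threshold overrides).
#' @param grid The [grid_spec()].
#' @param native,invasive Optional validation `occurrence_set`s for per-class
#'   hit counts.
#' @param cell_area Area of one cell (default `cell_size^2`; for geographic
#'   grids pass the cell area at the equator).
#' @return An object of class `ensemble_product`: list with `class_map`,
#'   `labels`, and `summary` (per-class data.frame).
#' @export
compose_susceptibility_map <- function(selected_opms, grid,
                                       native = NULL, invasive = NULL,
                                       cell_area = grid$cell_size^2) {
  stopifnot(length(selected_opms) >= 1)
  k <- length(selected_opms)
  if (k >= 2) {
    for (i in seq_len(k - 1)) {
      a <- selected_opms[[i]]; b <- selected_opms[[i + 1]]
      if (any(b == 1 & a == 0, na.rm = TRUE)) {
        warning("selected OPMs are not nested (", i + 1, " exceeds ", i, ")")
        break
      }
    }
  }
  class_map <- build_alm(selected_opms)
  labels <- susceptibility_labels(k)
  counts <- vapply(0:k, function(cl) sum(class_map == cl, na.rm = TRUE),
                   numeric(1))
  summary <- data.frame(class = 0:k, label = unname(labels),
                        n_cells = counts, area = counts * cell_area)
  count_hits <- function(pts) {
    if (is.null(pts) || nrow(pts) == 0) return(rep(NA_integer_, k + 1))
    v <- extract_cell_values(class_map, pts, grid)
    vapply(0:k, function(cl) sum(v == cl, na.rm = TRUE), integer(1))
  }
  summary$native_hits <- count_hits(native)
  summary$invasive_hits <- count_hits(invasive)
  structure(list(class_map = class_map, labels = labels, summary = summary),
            class = "ensemble_product")
}

#' @export
print.ensemble_product <- function(x, ...) {
  cat(sprintf("<ensemble_product> %d susceptibility classes\n",
              nrow(x$summary)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
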