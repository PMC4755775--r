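#' Define a raster grid
#'
#' A `grid_spec` describes the co-registered raster universe every spatial
#' object in a run lives on: extent, resolution and coordinate kind. Cell
#' membership is half-open: a point on a shared vertical edge belongs to the
#' cell to its right, a point on a shared horizontal edge to the cell below.
#' Cells are indexed row-major from the top-left cell (row 1, column 1).
#'
#' @param n_rows,n_cols Grid dimensions (>= 1).
#' @param x_min,y_min Coordinates of the lower-left corner.
#' @param cell_size Cell edge length (> 0); cells are square.
#' @param crs Either `"geographic"` (decimal degrees, WGS84 assumed; distances
#'   computed on the sphere) or `"planar"` (distances Euclidean).
#' @param nodata Sentinel value marking missing cells in layer files.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, x_min = 0, y_min = 0, cell_size = 1,
                      crs = c("planar", "geographic"), nodata = -9999) {
  crs <- match.arg(crs)
  stopifnot(n_rows >= 1, n_cols >= 1, cell_size > 0)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 x_min = x_min, y_min = y_min, cell_size = cell_size,
                 crs = crs, nodata = nodata),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells, cell size %g (%s)\n",
              x$n_rows, x$n_cols, x$cell_size, x$crs))
  cat(sprintf("  extent: x [%g, %g], y [%g, %g]\n",
              x$x_min, x$x_min + x$n_cols * x$cell_size,
              x$y_min, x$y_min + x$n_rows * x$cell_size))
  invisible(x)
}

grid_x_max <- function(grid) grid$x_min + grid$n_cols * grid$cell_size
grid_y_max <- function(grid) grid$y_min + grid$n_rows * grid$cell_size

#' Locate points on a grid
#'
#' Maps coordinates to (row, col, cell) indices under the half-open membership
#' rule. Points outside the extent get `NA`.
#'
#' @param grid A [grid_spec()].
#' @param x,y Coordinate vectors of equal length.
#' @return A data.frame with columns `row`, `col`, `cell` (row-major, 1-based).
#' @export
cell_index <- function(grid, x, y) {
  col <- floor((x - grid$x_min) / grid$cell_size) + 1L
  # horizontal edges belong to the cell below (larger row index)
  row <- floor((grid_y_max(grid) - y) / grid$cell_size) + 1L
  off <- col < 1L | col > grid$n_cols | row < 1L | row > grid$n_rows |
    !is.finite(x) | !is.finite(y)
  row[off] <- NA_integer_
  col[off] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col),
             cell = as.integer((row - 1L) * grid$n_cols + col))
}

#' Cell centroids
#'
#' @param grid A [grid_spec()].
#' @param row,col Cell indices (1-based, row 1 at the top).
#' @return A data.frame with centroid columns `x`, `y`.
#' @export
cell_centroid <- function(grid, row, col) {
  data.frame(x = grid$x_min + (col - 0.5) * grid$cell_size,
             y = grid_y_max(grid) - (row - 0.5) * grid$cell_size)
}

#' Assemble a layer stack
#'
#' Bundles co-registered environmental layers with the grid they live on and
#' the analyzable-cell mask. A cell is analyzable iff every layer holds a
#' finite, non-nodata value there and the optional exclusion mask allows it.
#'
#' @param grid A [grid_spec()].
#' @param layers Named list of numeric matrices (`n_rows` x `n_cols`, row 1 =
#'   top row). Values equal to `grid$nodata` are treated as missing.
#' @param exclusion Optional logical matrix, `TRUE` where cells are excluded
#'   (e.g. water bodies).
#' @return An object of class `layer_stack` with elements `grid`, `layers`
#'   (nodata recoded to `NA`), and `mask` (logical, `TRUE` = analyzable).
#' @export
layer_stack <- function(grid, layers, exclusion = NULL) {
  stopifnot(inherits(grid, "grid_spec"), is.list(layers), length(layers) >= 1)
  if (is.null(names(layers)) || any(!nzchar(names(layers))))
    stop("all layers must be named")
  dims <- c(grid$n_rows, grid$n_cols)
  layers <- lapply(layers, function(m) {
    m <- as.matrix(m)
    if (!all(dim(m) == dims)) stop("layer dimensions do not match the grid")
    m[m == grid$nodata] <- NA_real_
    storage.mode(m) <- "double"
    m
  })
  mask <- Reduce(`&`, lapply(layers, is.finite))
  if (!is.null(exclusion)) {
    exclusion <- as.matrix(exclusion)
    if (!all(dim(exclusion) == dims))
      stop("exclusion mask dimensions do not match the grid")
    mask <- mask & !exclusion
  }
  if (!any(mask)) stop("no analyzable cells in the stack")
  structure(list(grid = grid, layers = layers, mask = mask),
            class = "layer_stack")
}

#' @export
print.layer_stack <- function(x, ...) {
  cat(sprintf("<layer_stack> %d layer(s) on a %d x %d grid, %d analyzable cells\n",
              length(x$layers), x$grid$n_rows, x$grid$n_cols, sum(x$mask)))
  cat("  layers:", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

n_analyzable <- function(stack) sum(stack$mask)

#' Prune collinear layers
#'
#' Removes layers until no pair has |Pearson r| at or above `r_max`, computed
#' over analyzable cells only. Offending pairs are visited in descending |r|;
#' within a pair the layer with the larger mean absolute correlation against
#' all currently retained layers is dropped, ties keeping the earlier layer in
#' input order. The rule is deterministic and idempotent; input layer order is
#' preserved among survivors.
#'
#' @param stack A [layer_stack()] with at least two layers.
#' @param r_max Correlation threshold in (0, 1]; pairs with |r| >= `r_max`
#'   trigger a drop. Default 0.75.
#' @return The pruned `layer_stack`, with attribute `"dropped"` naming removed
#'   layers.
#' @export
prune_collinear_layers <- function(stack, r_max = 0.75) {
  stopifnot(inherits(stack, "layer_stack"), length(stack$layers) >= 2,
            r_max > 0, r_max <= 1)
  vals <- vapply(stack$layers, function(m) m[stack$mask],
                 numeric(n_analyzable(stack)))
  sds <- apply(vals, 2, stats::sd)
  if (any(sds == 0))
    stop("layer(s) constant over analyzable cells, correlation undefined: ",
         paste(colnames(vals)[sds == 0], collapse = ", "))
  cmat <- abs(stats::cor(vals))
  keep <- rep(TRUE, ncol(cmat))
  names(keep) <- colnames(cmat)
  repeat {
    sub <- cmat[keep, keep, drop = FALSE]
    diag(sub) <- 0
    if (all(sub < r_max)) break
    worst <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    pair <- rownames(sub)[worst]
    # drop the member more correlated on average with everything retained
    mean_r <- vapply(pair, function(nm) {
      others <- setdiff(rownames(sub), nm)
      mean(cmat[nm, others])
    }, numeric(1))
    drop_nm <- if (mean_r[2] > mean_r[1]) pair[2] else pair[1]
    keep[drop_nm] <- FALSE
  }
  out <- stack
  out$layers <- stack$layers[names(keep)[keep]]
  # mask unchanged: analyzability defined on the original stack
  attr(out, "dropped") <- names(keep)[!keep]
  out
}

as_occurrence_set <- function(df, deduplicated = FALSE) {
  stopifnot(all(c("id", "x", "y", "role") %in% names(df)))
  roles <- c("native_presence", "invasive_presence", "other_species", "random_pa")
  bad <- setdiff(unique(df$role), roles)
  if (length(bad)) stop("unknown role(s): ", paste(bad, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  structure(df, class = c("occurrence_set", "data.frame"),
            deduplicated = deduplicated)
}

#' Build a role-tagged occurrence set
#'
#' @param x,y Coordinate vectors.
#' @param role One of `"native_presence"`, `"invasive_presence"`,
#'   `"other_species"`, `"random_pa"` (recycled).
#' @param id Optional record identifiers (default sequential).
#' @return An `occurrence_set` (a data.frame with columns id, x, y, role).
#' @export
occurrence_set <- function(x, y, role, id = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (is.null(id)) id <- seq_len(n)
  as_occurrence_set(data.frame(id = id, x = x, y = y,
                               role = rep_len(role, n),
                               stringsAsFactors = FALSE))
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("<occurrence_set> %d record(s)%s\n", nrow(x),
              if (isTRUE(attr(x, "deduplicated"))) ", deduplicated to cells" else ""))
  print(table(x$role))
  invisible(x)
}

#' Remove records off-grid or on excluded cells
#'
#' Drops records falling outside the grid extent, on nodata cells, or on
#' mask-excluded (e.g. water) cells, and logs a removal reason per dropped
#' record.
#'
#' @param points An `occurrence_set`.
#' @param stack A [layer_stack()]; its mask defines analyzable cells.
#' @return The cleaned `occurrence_set`; attribute `"cleaning_log"` is a
#'   data.frame (id, reason) of removals.
#' @export
clean_records <- function(points, stack) {
  stopifnot(inherits(points, "occurrence_set"), inherits(stack, "layer_stack"))
  if (nrow(points) == 0) {
    attr(points, "cleaning_log") <- data.frame(id = integer(), reason = character())
    return(points)
  }
  idx <- cell_index(stack$grid, points$x, points$y)
  reason <- rep(NA_character_, nrow(points))
  reason[is.na(idx$cell)] <- "outside_extent"
  inside <- which(is.na(reason))
  excl <- inside[!stack$mask[cbind(idx$row[inside], idx$col[inside])]]
  reason[excl] <- "excluded_cell"
  keep <- is.na(reason)
  out <- as_occurrence_set(points[keep, , drop = FALSE],
                           deduplicated = isTRUE(attr(points, "deduplicated")))
  attr(out, "cleaning_log") <- data.frame(id = points$id[!keep],
                                          reason = reason[!keep],
                                          stringsAsFactors = FALSE)
  out
}

#' Deduplicate occurrences to grid cells
#'
#' The fishnet treatment: each occupied (role, cell) pair becomes a single
#' record located at the cell centroid. Records off-grid or on non-analyzable
#' cells are removed first (via [clean_records()]) and counted.
#'
#' @param points An `occurrence_set`.
#' @param stack A [layer_stack()].
#' @return A deduplicated `occurrence_set` with extra columns `row`, `col`,
#'   `cell`; attributes `"n_removed"` and `"n_merged"` count records dropped by
#'   cleaning and collapsed by deduplication.
#' @export
dedup_to_cells <- function(points, stack) {
  cleaned <- clean_records(points, stack)
  n_removed <- nrow(points) - nrow(cleaned)
  if (nrow(cleaned) == 0) {
    out <- cbind(as.data.frame(cleaned),
                 data.frame(row = integer(), col = integer(), cell = integer()))
    out <- as_occurrence_set(out, deduplicated = TRUE)
    attr(out, "n_removed") <- n_removed
    attr(out, "n_merged") <- 0L
    return(out)
  }
  idx <- cell_index(stack$grid, cleaned$x, cleaned$y)
  key <- paste(cleaned$role, idx$cell)
  first <- !duplicated(key)
  kept <- cleaned[first, , drop = FALSE]
  kidx <- idx[first, , drop = FALSE]
  cen <- cell_centroid(stack$grid, kidx$row, kidx$col)
  kept$x <- cen$x
  kept$y <- cen$y
  out <- cbind(as.data.frame(kept), kidx)
  out <- as_occurrence_set(out, deduplicated = TRUE)
  attr(out, "n_removed") <- n_removed
  attr(out, "n_merged") <- sum(!first)
  out
}

#' Extract cell values under points
#'
#' Plain cell lookup of a per-cell map at point locations, in input order.
#'
#' @param map Numeric matrix on the stack's grid.
#' @param points A deduplicated, on-grid `occurrence_set` (run
#'   [dedup_to_cells()] first).
#' @param grid The [grid_spec()] the map lives on.
#' @return Numeric vector of containing-cell values.
#' @export
extract_cell_values <- function(map, points, grid) {
  stopifnot(inherits(points, "occurrence_set"))
  if (nrow(points) == 0) return(numeric(0))
  idx <- if (all(c("row", "col") %in% names(points))) {
    points[, c("row", "col")]
  } else {
    cell_index(grid, points$x, points$y)
  }
  if (anyNA(idx$row)) stop("point(s) off the grid; run clean_records first")
  map[cbind(idx$row, idx$col)]
}
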