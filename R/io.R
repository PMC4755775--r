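#' Read an ESRI ASCII grid
#'
#' Single-band plain-text raster with the standard six-line header
#' (`ncols`, `nrows`, `xllcorner`/`xllcenter`, `yllcorner`/`yllcenter`,
#' `cellsize`, `NODATA_value`). Nodata cells become `NA`.
#'
#' @param path File path.
#' @param crs Coordinate kind for the resulting grid, `"planar"` or
#'   `"geographic"`.
#' @return A list with `grid` (a [grid_spec()]) and `values` (matrix, row 1 =
#'   top row).
#' @export
read_ascii_grid <- function(path, crs = "geographic") {
  lines <- readLines(path, n = 6)
  hdr <- list()
  n_hdr <- 0
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    key <- tolower(tok[1])
    if (key %in% c("ncols", "nrows", "xllcorner", "yllcorner", "xllcenter",
                   "yllcenter", "cellsize", "nodata_value")) {
      hdr[[key]] <- as.numeric(tok[2])
      n_hdr <- n_hdr + 1
    } else break
  }
  if (is.null(hdr$ncols) || is.null(hdr$nrows) || is.null(hdr$cellsize))
    stop("not an ESRI ASCII grid: ", path)
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  x_min <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else hdr$xllcenter - hdr$cellsize / 2
  y_min <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else hdr$yllcenter - hdr$cellsize / 2
  vals <- scan(path, what = numeric(), skip = n_hdr, quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("cell count mismatch in ", path)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  grid <- grid_spec(hdr$nrows, hdr$ncols, x_min, y_min, hdr$cellsize,
                    crs = crs, nodata = nodata)
  list(grid = grid, values = m)
}

#' Write an ESRI ASCII grid
#'
#' @param map Numeric matrix (row 1 = top row); `NA` written as nodata.
#' @param grid The [grid_spec()] the map lives on.
#' @param path Output file path.
#' @export
write_ascii_grid <- function(map, grid, path) {
  stopifnot(all(dim(map) == c(grid$n_rows, grid$n_cols)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", grid$n_cols),
               sprintf("nrows %d", grid$n_rows),
               sprintf("xllcorner %.10g", grid$x_min),
               sprintf("yllcorner %.10g", grid$y_min),
               sprintf("cellsize %.10g", grid$cell_size),
               sprintf("NODATA_value %.10g", grid$nodata)), con)
  map[is.na(map)] <- grid$nodata
  utils::write.table(map, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read occurrences from CSV
#'
#' Expects header columns `id`, `lon`, `lat`, `role` (or `x`/`y` in place of
#' `lon`/`lat` for planar data).
#'
#' @param path CSV file path.
#' @return An `occurrence_set`.
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (all(c("lon", "lat") %in% names(df))) {
    df$x <- df$lon; df$y <- df$lat
  }
  as_occurrence_set(df[, c("id", "x", "y", "role")])
}

#' Write occurrences to CSV
#'
#' @param points An `occurrence_set`.
#' @param path Output path.
#' @param geographic Write coordinate columns as `lon`/`lat` (default) or
#'   `x`/`y`.
#' @export
write_occurrences <- function(points, path, geographic = TRUE) {
  df <- as.data.frame(points)[, c("id", "x", "y", "role")]
  if (geographic) names(df)[2:3] <- c("lon", "lat")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
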