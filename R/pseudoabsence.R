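#' Pseudo-absence configuration
#'
#' Counting and spacing parameters for the two pseudo-absence datasets:
#' distance-filtered non-target-species records (BOPA) and constrained random
#' points (RPA). Defaults follow the bumblebee-invasion use case: a 10 km exclusion
#' radius (the longest recorded worker foraging displacement), 15 km minimum
#' spacing between random points, ten pseudo-absences per native presence, and
#' five replicated pseudo-absence subsets. Units are metres on geographic
#' grids and grid units on planar grids.
#'
#' @param exclusion_radius Distance below which a non-target record is too
#'   close to a presence to count as an absence; also the buffer radius of the
#'   restriction zone.
#' @param min_spacing Minimum pairwise distance between random pseudo-absence
#'   points.
#' @param pa_multiplier Target pseudo-absences per native presence per subset.
#' @param n_replications Number of pseudo-absence subsets k.
#' @param seed Integer seed for random-point generation.
#' @return An object of class `pa_config`.
#' @export
pa_config <- function(exclusion_radius = 10000, min_spacing = 15000,
                      pa_multiplier = 10, n_replications = 5, seed = 1L) {
  stopifnot(exclusion_radius > 0, min_spacing > 0, pa_multiplier >= 1,
            n_replications >= 1)
  structure(list(exclusion_radius = exclusion_radius,
                 min_spacing = min_spacing,
                 pa_multiplier = pa_multiplier,
                 n_replications = as.integer(n_replications),
                 seed = as.integer(seed)),
            class = "pa_config")
}

# pairwise point distances respecting the grid's coordinate kind
point_distances <- function(x1, y1, x2, y2, crs) {
  if (crs == "geographic") {
    geosphere::distm(cbind(x1, y1), cbind(x2, y2),
                     fun = geosphere::distHaversine)
  } else {
    outer(x1, x2, function(a, b) (a - b)^2) +
      outer(y1, y2, function(a, b) (a - b)^2) -> d2
    sqrt(d2)
  }
}

nearest_distance <- function(px, py, qx, qy, crs) {
  if (length(qx) == 0) return(rep(Inf, length(px)))
  d <- point_distances(px, py, qx, qy, crs)
  apply(d, 1, min)
}

#' Filter non-target records into reliable pseudo-absences
#'
#' Retains a non-target-species (BOPA) record iff its distance to the nearest
#' native presence is at least the exclusion radius; records strictly closer
#' are discarded (a sighting that near a presence could still be within the
#' species' displacement range). Distance is haversine on geographic grids,
#' Euclidean on planar grids.
#'
#' @param other_species `occurrence_set` of non-target records (deduplicated).
#' @param native `occurrence_set` of native presences (deduplicated).
#' @param cfg A [pa_config()].
#' @param crs `"geographic"` or `"planar"`.
#' @return The retained `occurrence_set`; attribute `"n_excluded"` counts
#'   removals.
#' @export
filter_bopa <- function(other_species, native, cfg, crs = "geographic") {
  stopifnot(inherits(other_species, "occurrence_set"),
            inherits(native, "occurrence_set"))
  if (nrow(native) == 0) {
    warning("empty native set: all non-target records retained")
    attr(other_species, "n_excluded") <- 0L
    return(other_species)
  }
  d <- nearest_distance(other_species$x, other_species$y,
                        native$x, native$y, crs)
  keep <- d >= cfg$exclusion_radius
  out <- as_occurrence_set(other_species[keep, , drop = FALSE],
                           deduplicated = isTRUE(attr(other_species, "deduplicated")))
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Build the random-point restriction zone
#'
#' The union of exclusion-radius disks around every native presence and every
#' retained BOPA record. Random pseudo-absences must fall outside this zone.
#' Invasive presences are deliberately not buffered (the invaded range is the
#' validation region, not a fitting input) and are rejected if passed in.
#'
#' @param native Native presences (`occurrence_set`).
#' @param bopa Retained BOPA records (`occurrence_set`).
#' @param cfg A [pa_config()].
#' @param crs `"geographic"` or `"planar"`.
#' @return An object of class `restriction_zone` (buffer centers + radius)
#'   supporting [zone_contains()] and [zone_wkt()].
#' @export
build_restriction_zone <- function(native, bopa, cfg, crs = "geographic") {
  pts <- rbind(as.data.frame(native)[, c("x", "y", "role")],
               as.data.frame(bopa)[, c("x", "y", "role")])
  if (any(pts$role == "invasive_presence"))
    stop("invasive presences must not define the restriction zone")
  structure(list(x = pts$x, y = pts$y, radius = cfg$exclusion_radius,
                 crs = crs),
            class = "restriction_zone")
}

#' Test membership in a restriction zone
#'
#' A point is inside the zone iff its distance to the nearest buffer center is
#' strictly less than the buffer radius (points exactly on the boundary are
#' outside, mirroring the retention rule of [filter_bopa()]).
#'
#' @param zone A `restriction_zone`.
#' @param x,y Probe coordinates.
#' @return Logical vector.
#' @export
zone_contains <- function(zone, x, y) {
  if (length(zone$x) == 0) return(rep(FALSE, length(x)))
  nearest_distance(x, y, zone$x, zone$y, zone$crs) < zone$radius
}

#' Export a restriction zone as Well-Known Text
#'
#' Writes each buffer disk as a closed 64-gon `POLYGON` inside a
#' `GEOMETRYCOLLECTION`. On geographic grids the polygon is built with
#' geodesic destination points; on planar grids with circle coordinates.
#'
#' @param zone A `restriction_zone`.
#' @param n_vertices Vertices per disk polygon.
#' @return A WKT string.
#' @export
zone_wkt <- function(zone, n_vertices = 64) {
  ang <- seq(0, 360, length.out = n_vertices + 1)
  polys <- vapply(seq_along(zone$x), function(i) {
    if (zone$crs == "geographic") {
      ring <- geosphere::destPoint(c(zone$x[i], zone$y[i]), ang, zone$radius)
    } else {
      th <- ang * pi / 180
      ring <- cbind(zone$x[i] + zone$radius * sin(th),
                    zone$y[i] + zone$radius * cos(th))
    }
    sprintf("POLYGON ((%s))",
            paste(sprintf("%.8g %.8g", ring[, 1], ring[, 2]), collapse = ", "))
  }, character(1))
  sprintf("GEOMETRYCOLLECTION (%s)", paste(polys, collapse = ", "))
}

#' Count the random pseudo-absences to generate
#'
#' The study's counting rule: the total random pseudo-absence count is
#' `multiplier * n_native * k - k * n_bopa`, so that after the BOPA records
#' are appended to each of the k random subsets, every subset holds exactly
#' `multiplier * n_native` pseudo-absences.
#'
#' @param n_native Number of native presence cells.
#' @param n_bopa Number of retained BOPA records.
#' @param cfg A [pa_config()].
#' @return Integer total (divisible by k by construction).
#' @export
compute_rpa_count <- function(n_native, n_bopa, cfg) {
  total <- cfg$pa_multiplier * n_native * cfg$n_replications -
    cfg$n_replications * n_bopa
  if (total < 0)
    stop("more BOPA records than target pseudo-absences per subset (",
         n_bopa, " > ", cfg$pa_multiplier * n_native, ")")
  as.integer(total)
}

#' Generate constrained random pseudo-absence points
#'
#' Rejection-samples exactly `n` points that (i) lie inside the layer extent
#' on analyzable cells, (ii) fall outside the restriction zone, and (iii) keep
#' a pairwise distance of at least `cfg$min_spacing` (which also caps density
#' at about one point per cell at the study scale). Proposals are uniform over
#' analyzable cells with uniform within-cell jitter; spacing is enforced with
#' a bucket grid so only neighbouring buckets are checked. Reproducible for a
#' fixed `cfg$seed`.
#'
#' @param stack A [layer_stack()].
#' @param zone A `restriction_zone` (may hold zero buffers).
#' @param n Number of points required.
#' @param cfg A [pa_config()].
#' @return An `occurrence_set` with role `random_pa`.
#' @export
generate_random_pa <- function(stack, zone, n, cfg) {
  stopifnot(n >= 1)
  grid <- stack$grid
  ok <- which(stack$mask)                       # column-major indices
  if (length(ok) == 0) stop("no analyzable cells")
  rows <- ((ok - 1L) %% grid$n_rows) + 1L
  cols <- ((ok - 1L) %/% grid$n_rows) + 1L
  # exclude cells whose centroid sits inside the zone early (cheap pre-filter;
  # the exact per-point test still runs on each jittered proposal)
  cen <- cell_centroid(grid, rows, cols)
  if (length(zone$x) > 0) {
    free <- !zone_contains(zone, cen$x, cen$y)
    if (!any(free)) stop("restriction zone covers every analyzable cell; 0 of ",
                         n, " points achieved")
    rows <- rows[free]; cols <- cols[free]
  }
  # bucket grid for the spacing test: bucket edge >= spacing so only the
  # 3x3 neighbourhood needs checking
  spacing <- cfg$min_spacing
  if (grid$crs == "geographic") {
    # conservative planar proxy in degrees at the highest latitude of the grid
    deg_per_m_lat <- 1 / 111194.9
    bucket <- spacing * deg_per_m_lat
  } else {
    bucket <- spacing
  }
  bx0 <- grid$x_min; by0 <- grid$y_min
  accepted_x <- numeric(n); accepted_y <- numeric(n)
  buckets <- new.env(hash = TRUE, parent = emptyenv())
  n_acc <- 0L
  budget <- 1000 * n
  set.seed(cfg$seed)
  tries <- 0L
  while (n_acc < n && tries < budget) {
    m <- min(max(1000L, n - n_acc), budget - tries)
    tries <- tries + m
    pick <- sample.int(length(rows), m, replace = TRUE)
    px <- grid$x_min + (cols[pick] - 1L + stats::runif(m)) * grid$cell_size
    py <- grid_y_max(grid) - (rows[pick] - 1L + stats::runif(m)) * grid$cell_size
    inzone <- zone_contains(zone, px, py)
    for (j in which(!inzone)) {
      bi <- floor((px[j] - bx0) / bucket); bj <- floor((py[j] - by0) / bucket)
      clash <- FALSE
      for (di in -1:1) {
        for (dj in -1:1) {
          key <- paste(bi + di, bj + dj)
          idxs <- buckets[[key]]
          if (!is.null(idxs)) {
            d <- point_distances(px[j], py[j],
                                 accepted_x[idxs], accepted_y[idxs], grid$crs)
            if (any(d < spacing)) { clash <- TRUE; break }
          }
        }
        if (clash) break
      }
      if (!clash) {
        n_acc <- n_acc + 1L
        accepted_x[n_acc] <- px[j]; accepted_y[n_acc] <- py[j]
        key <- paste(bi, bj)
        buckets[[key]] <- c(buckets[[key]], n_acc)
        if (n_acc == n) break
      }
    }
  }
  if (n_acc < n)
    stop("rejection budget exhausted: ", n_acc, " of ", n, " points achieved")
  occurrence_set(accepted_x[seq_len(n)], accepted_y[seq_len(n)], "random_pa")
}

#' Partition random pseudo-absences into replicated subsets
#'
#' Splits the random points into k equal disjoint fractions (seeded
#' permutation, contiguous slices) and appends the full BOPA set to each, so
#' every subset holds `|random|/k + |bopa|` records.
#'
#' @param random_pa `occurrence_set` of random points; count divisible by k.
#' @param bopa Retained BOPA records.
#' @param cfg A [pa_config()].
#' @return List of k `occurrence_set`s; each has attribute `"source"` marking
#'   rows as `"random"` or `"bopa"`.
#' @export
build_pa_subsets <- function(random_pa, bopa, cfg) {
  k <- cfg$n_replications
  n <- nrow(random_pa)
  if (n %% k != 0)
    stop("random pseudo-absence count (", n, ") not divisible by k = ", k)
  set.seed(cfg$seed + 1L)
  perm <- sample.int(n)
  per <- n %/% k
  lapply(seq_len(k), function(i) {
    idx <- perm[((i - 1L) * per + 1L):(i * per)]
    keep_cols <- c("id", "x", "y", "role")
    sub <- rbind(as.data.frame(random_pa)[idx, keep_cols, drop = FALSE],
                 as.data.frame(bopa)[, keep_cols, drop = FALSE])
    sub$role <- "random_pa"  # unified absence label for fitting
    out <- as_occurrence_set(sub, deduplicated = TRUE)
    attr(out, "source") <- c(rep("random", per), rep("bopa", nrow(bopa)))
    out
  })
}
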