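test_that("BOPA filtering keeps records at or beyond the exclusion radius", {
  cfg <- pa_config(exclusion_radius = 10000)   # metres, geographic
  native <- occurrence_set(0, 0, "native_presence")
  # ~5 km, ~10.1 km and exactly-at-radius points due east of the presence
  deg <- function(m) m / (111194.9)            # metres per degree at equator
  bopa <- occurrence_set(c(deg(5000), deg(10100)), c(0, 0), "other_species")
  kept <- filter_bopa(bopa, native, cfg, crs = "geographic")
  expect_equal(nrow(kept), 1L)
  expect_equal(attr(kept, "n_excluded"), 1L)
  # planar: boundary distance d == radius is retained (strictly-less excluded)
  cfgp <- pa_config(exclusion_radius = 2)
  bopa_p <- occurrence_set(c(2, 1.999), c(0, 0), "other_species")
  kept_p <- filter_bopa(bopa_p, occurrence_set(0, 0, "native_presence"),
                        cfgp, crs = "planar")
  expect_equal(kept_p$x, 2)
  # empty native set warns and retains everything
  expect_warning(all_kept <- filter_bopa(bopa, occurrence_set(
    numeric(0), numeric(0), character(0)), cfg), "empty native")
  expect_equal(nrow(all_kept), 2L)
})

test_that("BOPA filtering agrees with an all-pairs haversine oracle", {
  cfg <- pa_config(exclusion_radius = 10000)
  set.seed(31)
  native <- occurrence_set(runif(20, -1, 1), runif(20, -1, 1),
                           "native_presence")
  bopa <- occurrence_set(runif(50, -1, 1), runif(50, -1, 1), "other_species")
  kept <- filter_bopa(bopa, native, cfg, crs = "geographic")
  hav <- function(lon1, lat1, lon2, lat2) {
    r <- 6378137   # geosphere default radius
    to <- pi / 180
    a <- sin((lat2 - lat1) * to / 2)^2 +
      cos(lat1 * to) * cos(lat2 * to) * sin((lon2 - lon1) * to / 2)^2
    2 * r * asin(sqrt(a))
  }
  keep_oracle <- vapply(seq_len(nrow(bopa)), function(i) {
    d <- vapply(seq_len(nrow(native)), function(j)
      hav(bopa$x[i], bopa$y[i], native$x[j], native$y[j]), numeric(1))
    min(d) >= 10000
  }, logical(1))
  expect_equal(kept$id, bopa$id[keep_oracle])
})

test_that("restriction zone is the union of buffers and rejects invasive input", {
  cfg <- pa_config(exclusion_radius = 2)
  native <- occurrence_set(c(3, 7), c(5, 5), "native_presence")
  bopa <- occurrence_set(numeric(0), numeric(0), character(0))
  zone <- build_restriction_zone(native, bopa, cfg, crs = "planar")
  # membership of 1000 probes equals the nearest-distance oracle
  set.seed(8)
  px <- runif(1000, 0, 10); py <- runif(1000, 0, 10)
  got <- zone_contains(zone, px, py)
  oracle <- pmin(sqrt((px - 3)^2 + (py - 5)^2),
                 sqrt((px - 7)^2 + (py - 5)^2)) < 2
  expect_equal(got, oracle)
  # invasive presences must never define the zone
  inv <- occurrence_set(1, 1, "invasive_presence")
  expect_error(build_restriction_zone(native, inv, cfg, crs = "planar"),
               "invasive")
  # WKT export carries one polygon per buffer
  wkt <- zone_wkt(zone)
  expect_match(wkt, "^GEOMETRYCOLLECTION ")
  expect_equal(lengths(regmatches(wkt, gregexpr("POLYGON", wkt))), 2L)
})

test_that("random pseudo-absence counting follows the study formula", {
  cfg5 <- pa_config(pa_multiplier = 10, n_replications = 5)
  expect_equal(compute_rpa_count(100, 30, cfg5), 4850L)   # (10*100*5) - 5*30
  cfg1 <- pa_config(pa_multiplier = 10, n_replications = 1)
  expect_equal(compute_rpa_count(1, 0, cfg1), 10L)
  expect_equal(compute_rpa_count(100, 30, cfg5) %% 5, 0L)
  expect_error(compute_rpa_count(1, 20, cfg5), "more BOPA")
})

test_that("random points satisfy every spatial constraint", {
  stack <- make_test_stack(40, 40, seed = 13)
  cfg <- pa_config(exclusion_radius = 3, min_spacing = 2, seed = 99)
  native <- dedup_to_cells(random_points(12, stack$grid, seed = 14), stack)
  zone <- build_restriction_zone(
    native, occurrence_set(numeric(0), numeric(0), character(0)),
    cfg, crs = "planar")
  pa <- generate_random_pa(stack, zone, 200, cfg)
  expect_equal(nrow(pa), 200L)
  # oracle 1: all inside extent on analyzable cells
  idx <- cell_index(stack$grid, pa$x, pa$y)
  expect_false(anyNA(idx$cell))
  # oracle 2: outside the zone (per-point nearest distance)
  for (i in seq_len(nrow(pa))) {
    d <- sqrt((pa$x[i] - native$x)^2 + (pa$y[i] - native$y)^2)
    expect_gte(min(d), 3)
  }
  # oracle 3: pairwise spacing
  dm <- as.matrix(dist(cbind(pa$x, pa$y)))
  diag(dm) <- Inf
  expect_gte(min(dm), 2)
  # bit-reproducible per seed
  pa2 <- generate_random_pa(stack, zone, 200, cfg)
  expect_identical(pa$x, pa2$x)
  expect_identical(pa$y, pa2$y)
})

test_that("infeasible constraints abort with the achieved count", {
  stack <- make_test_stack(5, 5)
  cfg <- pa_config(exclusion_radius = 50, min_spacing = 1, seed = 1)
  zone <- build_restriction_zone(
    occurrence_set(2.5, 2.5, "native_presence"),
    occurrence_set(numeric(0), numeric(0), character(0)), cfg, crs = "planar")
  expect_error(generate_random_pa(stack, zone, 5, cfg), "0 of 5")
})

test_that("pseudo-absence subsets partition the random points", {
  stack <- make_test_stack(30, 30, seed = 21)
  cfg <- pa_config(exclusion_radius = 2, min_spacing = 1,
                   pa_multiplier = 5, n_replications = 5, seed = 7)
  empty <- occurrence_set(numeric(0), numeric(0), character(0))
  zone <- build_restriction_zone(empty, empty, cfg, crs = "planar")
  rand <- generate_random_pa(stack, zone, 100, cfg)
  bopa <- dedup_to_cells(random_points(9, stack$grid, seed = 3,
                                       role = "other_species"), stack)[1:7, ]
  subs <- build_pa_subsets(rand, bopa, cfg)
  expect_length(subs, 5L)
  expect_true(all(vapply(subs, nrow, integer(1)) == 27L))   # 100/5 + 7
  # random fractions are pairwise disjoint and their union is the full set
  rand_parts <- lapply(subs, function(s) {
    src <- attr(s, "source")
    paste(s$x[src == "random"], s$y[src == "random"])
  })
  expect_length(unique(unlist(rand_parts)), 100L)
  for (i in 1:4) for (j in (i + 1):5)
    expect_length(intersect(rand_parts[[i]], rand_parts[[j]]), 0L)
  # k = 1 keeps everything together
  cfg1 <- pa_config(n_replications = 1, seed = 7)
  expect_equal(nrow(build_pa_subsets(rand, bopa, cfg1)[[1]]), 107L)
  # non-divisible counts are rejected
  expect_error(build_pa_subsets(rand[1:99, ], bopa, cfg), "divisible")
})

test_that("retained BOPA records never lie inside the restriction zone", {
  stack <- make_test_stack(30, 30, seed = 23)
  cfg <- pa_config(exclusion_radius = 3, min_spacing = 1, seed = 5)
  native <- dedup_to_cells(random_points(15, stack$grid, seed = 2), stack)
  other <- dedup_to_cells(random_points(60, stack$grid, seed = 6,
                                        role = "other_species"), stack)
  bopa <- filter_bopa(other, native, cfg, crs = "planar")
  zone <- build_restriction_zone(native, bopa, cfg, crs = "planar")
  # zone buffers native points at the exclusion radius, so retained BOPA
  # cannot fall inside the native part of the zone
  nz <- build_restriction_zone(
    native, occurrence_set(numeric(0), numeric(0), character(0)),
    cfg, crs = "planar")
  expect_false(any(zone_contains(nz, bopa$x, bopa$y)))
})
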