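#' Generate spatially autocorrelated environmental layers
#'
#' Builds Gaussian random fields by circular FFT smoothing of white noise
#' with a Gaussian kernel, then mixes the standardized fields through the
#' Cholesky factor of a target correlation matrix. Field columns are
#' orthonormalized before mixing, so the realized inter-layer correlations
#' match the target exactly (up to rescaling); spatial autocorrelation range
#' is set by the kernel scale in cell units. Deterministic per seed.
#'
#' @param grid A [grid_spec()] (planar).
#' @param n_layers Number of layers (>= 2).
#' @param autocorr_scale Gaussian kernel standard deviation, in cells.
#' @param inter_layer_corr Either a scalar target correlation applied to the
#'   first layer pair (others independent) or a full `n_layers` x `n_layers`
#'   correlation matrix. Must be positive definite.
#' @param seed Integer seed.
#' @return A [layer_stack()] with layers `env1` ... `envn`.
#' @export
make_layers <- function(grid, n_layers = 6, autocorr_scale = 8,
                        inter_layer_corr = 0, seed = 1L) {
  stopifnot(n_layers >= 2)
  if (length(inter_layer_corr) == 1) {
    corr <- diag(n_layers)
    corr[1, 2] <- corr[2, 1] <- inter_layer_corr
  } else {
    corr <- inter_layer_corr
    stopifnot(all(dim(corr) == n_layers))
  }
  ch <- tryCatch(chol(corr),
                 error = function(e) stop("correlation matrix not positive definite"))
  nr <- grid$n_rows; nc <- grid$n_cols
  # frequency response of a circular gaussian kernel
  dr <- pmin(0:(nr - 1), nr - 0:(nr - 1))
  dc <- pmin(0:(nc - 1), nc - 0:(nc - 1))
  kern <- exp(-0.5 * outer(dr, dc, function(a, b) (a^2 + b^2)) / autocorr_scale^2)
  kf <- stats::fft(kern / sum(kern))
  set.seed(seed)
  fields <- vapply(seq_len(n_layers), function(i) {
    z <- matrix(stats::rnorm(nr * nc), nr, nc)
    sm <- Re(stats::fft(stats::fft(z) * kf, inverse = TRUE)) / (nr * nc)
    as.vector(sm)
  }, numeric(nr * nc))
  # exact target correlation: orthonormalize, then mix
  q <- qr.Q(qr(scale(fields, center = TRUE, scale = FALSE)))
  mixed <- q %*% ch
  mixed <- scale(mixed)   # unit variance per layer
  layers <- lapply(seq_len(n_layers), function(i) matrix(mixed[, i], nr, nc))
  names(layers) <- paste0("env", seq_len(n_layers))
  layer_stack(grid, layers)
}

# Make the invaded window an environmental analog of the native band:
# copy a randomly placed congruent patch of the native region into the
# invaded window on every layer, plus independent smooth noise. This builds
# in the premise that the invaded region offers conditions the native range
# realizes (an analog climate on another landmass).
transplant_window <- function(stack, native_window, invaded_window,
                              noise_sd = 0.2, autocorr_scale = 5, seed = 1L) {
  grid <- stack$grid
  iw <- window_mask(grid, invaded_window)
  ridx <- which(apply(iw, 1, any)); cidx <- which(apply(iw, 2, any))
  h <- length(ridx); wdt <- length(cidx)
  nw <- window_mask(grid, native_window)
  nr_rows <- which(apply(nw, 1, any)); nr_cols <- which(apply(nw, 2, any))
  if (length(nr_rows) < h || length(nr_cols) < wdt)
    stop("native window too small to source an analog patch")
  set.seed(seed + 77L)
  r0 <- sample(seq_len(length(nr_rows) - h + 1), 1)
  c0 <- sample(seq_len(length(nr_cols) - wdt + 1), 1)
  src_r <- nr_rows[r0:(r0 + h - 1)]; src_c <- nr_cols[c0:(c0 + wdt - 1)]
  dr <- pmin(0:(h - 1), h - 0:(h - 1))
  dc <- pmin(0:(wdt - 1), wdt - 0:(wdt - 1))
  kern <- exp(-0.5 * outer(dr, dc, function(a, b) a^2 + b^2) / autocorr_scale^2)
  kf <- stats::fft(kern / sum(kern))
  for (nm in names(stack$layers)) {
    z <- matrix(stats::rnorm(h * wdt), h, wdt)
    sm <- Re(stats::fft(stats::fft(z) * kf, inverse = TRUE)) / (h * wdt)
    sm <- sm / stats::sd(sm)
    stack$layers[[nm]][ridx, cidx] <-
      stack$layers[[nm]][src_r, src_c] + noise_sd * sm
  }
  stack
}

#' Define a virtual species' niche and ground truth
#'
#' The virtual species responds to each named layer with an independent
#' Gaussian function; true suitability is the product of responses rescaled
#' to [0, 1] over analyzable cells, and the true range is the indicator of
#' suitability at or above `range_cut`. Niche conservatism between native and
#' invaded regions is exact by construction: the same response applies
#' everywhere.
#'
#' @param stack A [layer_stack()].
#' @param niche Named list: layer name -> `c(optimum, breadth)` (breadth = the
#'   Gaussian standard deviation, in layer units).
#' @param range_cut Suitability cut defining the true range, default 0.5.
#' @param native_window,invaded_window Disjoint rectangular sub-extents, each
#'   `c(x_min, x_max, y_min, y_max)`.
#' @return An object of class `virtual_truth`: list with `niche`,
#'   `true_suitability` (matrix), `true_range` (0/1 matrix), `range_cut`, and
#'   the two windows.
#' @export
make_truth <- function(stack, niche, range_cut = 0.5,
                       native_window, invaded_window) {
  missing_layers <- setdiff(names(niche), names(stack$layers))
  if (length(missing_layers))
    stop("niche references unknown layer(s): ",
         paste(missing_layers, collapse = ", "))
  if (windows_overlap(native_window, invaded_window))
    stop("native and invaded windows must be disjoint")
  suit <- matrix(1, stack$grid$n_rows, stack$grid$n_cols)
  for (nm in names(niche)) {
    p <- niche[[nm]]
    suit <- suit * exp(-0.5 * ((stack$layers[[nm]] - p[1]) / p[2])^2)
  }
  suit[!stack$mask] <- NA_real_
  mx <- max(suit, na.rm = TRUE)
  if (mx <= 0) stop("degenerate niche: zero suitability everywhere")
  suit <- suit / mx
  rng <- (suit >= range_cut) * 1
  for (w in list(native_window, invaded_window)) {
    inw <- window_mask(stack$grid, w)
    if (sum(rng == 1 & inw, na.rm = TRUE) == 0)
      stop("true range empty inside a sampling window; regenerate")
  }
  structure(list(niche = niche, true_suitability = suit, true_range = rng,
                 range_cut = range_cut, native_window = native_window,
                 invaded_window = invaded_window),
            class = "virtual_truth")
}

windows_overlap <- function(a, b) {
  a[1] < b[2] && b[1] < a[2] && a[3] < b[4] && b[3] < a[4]
}

# logical matrix of cells whose centroid falls inside the window
window_mask <- function(grid, w) {
  rows <- seq_len(grid$n_rows); cols <- seq_len(grid$n_cols)
  cx <- grid$x_min + (cols - 0.5) * grid$cell_size
  cy <- grid_y_max(grid) - (rows - 0.5) * grid$cell_size
  outer(cy >= w[3] & cy <= w[4], cx >= w[1] & cx <= w[2], `&`)
}

sample_window_points <- function(grid, mask, weights, window, n, seed_offset,
                                 seed) {
  inw <- window_mask(grid, window) & mask
  cells <- which(inw)
  if (length(cells) == 0) stop("sampling window holds no analyzable cells")
  w <- weights[cells]
  w[!is.finite(w)] <- 0
  if (sum(w) <= 0) stop("zero total sampling weight inside window")
  set.seed(seed + seed_offset)
  pick <- sample(cells, n, replace = TRUE, prob = w)
  rows <- ((pick - 1L) %% grid$n_rows) + 1L
  cols <- ((pick - 1L) %/% grid$n_rows) + 1L
  # jitter uniformly within the cell so deduplication has real work to do
  x <- grid$x_min + (cols - 1L + stats::runif(n)) * grid$cell_size
  y <- grid_y_max(grid) - (rows - 1L + stats::runif(n)) * grid$cell_size
  list(x = x, y = y)
}

#' Sample virtual-species occurrence records
#'
#' Native presences are drawn from the native window with sampling
#' probability proportional to true suitability; with probability
#' `detection_noise` a record is instead a false presence drawn uniformly
#' over the window. Invasive presences follow the same niche inside the
#' disjoint invaded window. Non-target-species records (the BOPA analogue:
#' surveys that found congeners but not the focal species) are drawn
#' uniformly over the native window — a broader tolerance occupying suitable
#' and unsuitable cells alike.
#'
#' @param truth A `virtual_truth`.
#' @param stack The [layer_stack()] the truth lives on.
#' @param n_native,n_invasive,n_other Record counts (>= 1).
#' @param detection_noise False-presence probability in [0, 1), default 0.02.
#' @param seed Integer seed.
#' @return List of `occurrence_set`s: `native`, `invasive`, `other`.
#' @export
sample_occurrences <- function(truth, stack, n_native = 500, n_invasive = 150,
                               n_other = 200, detection_noise = 0.02,
                               seed = 1L) {
  stopifnot(n_native >= 1, n_invasive >= 1, n_other >= 1,
            detection_noise >= 0, detection_noise < 1)
  grid <- stack$grid
  # occupied habitat: true-range cells, better cells sampled more often;
  # the noise fraction falls anywhere in the window (false presences)
  suit <- truth$true_suitability * (truth$true_range == 1)
  unif <- matrix(1, grid$n_rows, grid$n_cols)
  draw_presences <- function(window, n, offset) {
    set.seed(seed + offset)
    n_false <- stats::rbinom(1, n, detection_noise)
    p_true <- sample_window_points(grid, stack$mask, suit, window,
                                   n - n_false, offset + 1L, seed)
    if (n_false > 0) {
      p_false <- sample_window_points(grid, stack$mask, unif, window,
                                      n_false, offset + 2L, seed)
      list(x = c(p_true$x, p_false$x), y = c(p_true$y, p_false$y))
    } else p_true
  }
  nat <- draw_presences(truth$native_window, n_native, 100L)
  inv <- draw_presences(truth$invaded_window, n_invasive, 200L)
  oth <- sample_window_points(grid, stack$mask, unif, truth$native_window,
                              n_other, 300L, seed)
  list(native = occurrence_set(nat$x, nat$y, "native_presence"),
       invasive = occurrence_set(inv$x, inv$y, "invasive_presence"),
       other = occurrence_set(oth$x, oth$y, "other_species"))
}

#' Build the default synthetic test world
#'
#' A fully specified virtual-species world with known ground truth: a 100 x
#' 100 planar grid, six autocorrelated environmental layers (one pair
#' strongly correlated so collinearity pruning has work to do), a
#' three-layer Gaussian niche, a native sampling window in the south-west
#' and a disjoint invaded window in the north-east, and occurrence samples
#' of 500 native, 150 invasive and 200 non-target records.
#'
#' @param seed Integer seed driving every random draw.
#' @param n_rows,n_cols Grid dimensions.
#' @param n_layers Number of environmental layers.
#' @param n_native,n_invasive,n_other Occurrence counts.
#' @param detection_noise False-presence probability.
#' @return List with `stack`, `truth`, and `occ` (list of occurrence sets).
#' @export
synthetic_world <- function(seed = 1L, n_rows = 100, n_cols = 100,
                            n_layers = 6, n_native = 500, n_invasive = 150,
                            n_other = 200, detection_noise = 0.02) {
  grid <- grid_spec(n_rows, n_cols, x_min = 0, y_min = 0, cell_size = 1,
                    crs = "planar")
  corr <- diag(n_layers)
  corr[1, 2] <- corr[2, 1] <- 0.9    # collinear pair for the pruning step
  # autocorrelation range small relative to the extent, mirroring the
  # climate-layer-range : global-extent ratio of real topoclimatic stacks
  stack <- make_layers(grid, n_layers = n_layers, autocorr_scale = 5,
                       inter_layer_corr = corr, seed = seed)
  # native region: a wide southern band (a thoroughly sampled continental
  # range); invaded region: a disjoint north-eastern corner built as an
  # environmental analog of part of the native band
  native_window <- c(0, n_cols, 0, n_rows * 0.45)
  invaded_window <- c(n_cols * 0.55, n_cols, n_rows * 0.55, n_rows)
  stack <- transplant_window(stack, native_window, invaded_window,
                             noise_sd = 0.2, autocorr_scale = 5, seed = seed)
  # gaussian niche: three strong axes, breadths sized so the true range
  # occupies a small fraction (~5-10%) of the landscape, the regime of real
  # global suitability maps, plus weak responses on the remaining layers so
  # no layer is pure regional noise a learner could key on
  niche <- list(env1 = c(0.1, 0.6), env3 = c(-0.1, 0.65), env5 = c(0, 0.65),
                env4 = c(0, 2.0), env6 = c(0, 2.0))
  truth <- make_truth(stack, niche, range_cut = 0.5,
                      native_window = native_window,
                      invaded_window = invaded_window)
  occ <- sample_occurrences(truth, stack, n_native = n_native,
                            n_invasive = n_invasive, n_other = n_other,
                            detection_noise = detection_noise, seed = seed)
  list(stack = stack, truth = truth, occ = occ)
}
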