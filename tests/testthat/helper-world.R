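# fixtures built in code: small grids, stacks and point sets shared by tests

make_test_grid <- function(n_rows = 10, n_cols = 10, cell = 1) {
  grid_spec(n_rows, n_cols, x_min = 0, y_min = 0, cell_size = cell,
            crs = "planar")
}

# deterministic small stack with optional masked cells
make_test_stack <- function(n_rows = 10, n_cols = 10, n_layers = 3, seed = 42,
                            masked_cells = NULL) {
  grid <- make_test_grid(n_rows, n_cols)
  set.seed(seed)
  layers <- stats::setNames(
    lapply(seq_len(n_layers), function(i)
      matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)),
    paste0("L", seq_len(n_layers)))
  excl <- NULL
  if (!is.null(masked_cells)) {
    excl <- matrix(FALSE, n_rows, n_cols)
    excl[masked_cells] <- TRUE
  }
  layer_stack(grid, layers, exclusion = excl)
}

random_points <- function(n, grid, seed = 1, role = "native_presence") {
  set.seed(seed)
  occurrence_set(runif(n, grid$x_min, grid$x_min + grid$n_cols * grid$cell_size),
                 runif(n, grid$y_min, grid$y_min + grid$n_rows * grid$cell_size),
                 role)
}

# random binary map over a stack's analyzable cells (guaranteed non-constant)
random_binary_map <- function(stack, seed, p = 0.4) {
  set.seed(seed)
  m <- matrix(NA_real_, stack$grid$n_rows, stack$grid$n_cols)
  v <- rbinom(sum(stack$mask), 1, p)
  if (all(v == v[1])) v[1] <- 1 - v[1]
  m[stack$mask] <- v
  m
}

# a minimal fitted-model stub for selection/ensemble tests
model_stub <- function(id, algo, binary_map, tss = 0.85, run = 1, pa = 1,
                       continuous_map = NULL) {
  structure(list(id = id, algo = algo, run = run, pa = pa,
                 continuous_map = continuous_map %||% binary_map,
                 threshold = 0.5, binary_map = binary_map,
                 eval = list(sensitivity = NA, specificity = NA, tss = tss),
                 saw_invasive = FALSE),
            class = "suscept_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
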