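# shared toy setup: stub models on a small stack with known binary maps
sel_fixture <- function(n_models = 10, seed = 50) {
  stack <- make_test_stack(15, 15, seed = seed)
  native <- dedup_to_cells(random_points(30, stack$grid, seed = seed + 1),
                           stack)
  invasive <- dedup_to_cells(
    random_points(20, stack$grid, seed = seed + 2,
                  role = "invasive_presence"), stack)
  models <- lapply(seq_len(n_models), function(i)
    model_stub(sprintf("m%02d", i), algo = c("a", "b")[1 + i %% 2],
               binary_map = random_binary_map(stack, seed = seed + 10 + i),
               tss = 0.7 + 0.03 * i))
  list(stack = stack, native = native, invasive = invasive, models = models)
}

test_that("stage 1 applies the TSS cut inclusively", {
  fx <- sel_fixture()
  res <- stage1_filter(fx$models, tss_min = 0.8, fx$invasive, fx$native,
                       fx$stack$grid)
  tssv <- vapply(fx$models, function(m) m$eval$tss, numeric(1))
  # comprehension oracle, boundary inclusive
  expect_setequal(res$retained,
                  vapply(fx$models, `[[`, character(1), "id")[tssv >= 0.8])
  # boundary behaviour: 0.80 retained, 0.799 dropped
  m <- list(model_stub("lo", "a", random_binary_map(fx$stack, 1), tss = 0.799),
            model_stub("hi", "a", random_binary_map(fx$stack, 2), tss = 0.80))
  r2 <- stage1_filter(m, 0.8, fx$invasive, fx$native, fx$stack$grid)
  expect_equal(r2$retained, "hi")
  # idempotence
  kept <- fx$models[vapply(fx$models, `[[`, character(1), "id") %in%
                      res$retained]
  res2 <- stage1_filter(kept, 0.8, fx$invasive, fx$native, fx$stack$grid)
  expect_setequal(res2$retained, res$retained)
})

test_that("stage 2 retains models with IHR at or above the candidate mean", {
  fx <- sel_fixture(n_models = 20, seed = 70)
  res <- stage2_filter(fx$models, fx$invasive, fx$native, fx$stack$grid)
  ihr <- vapply(fx$models, function(m)
    hit_rate(m$binary_map, fx$invasive, fx$stack$grid), numeric(1))
  expect_equal(unname(attr(res, "cut")), mean(ihr))
  expect_setequal(res$retained,
                  vapply(fx$models, `[[`, character(1), "id")[ihr >= mean(ihr)])
  # equal-IHR models are all retained (IHR == mean)
  same <- lapply(1:3, function(i)
    model_stub(paste0("s", i), "a", fx$models[[1]]$binary_map))
  expect_length(stage2_filter(same, fx$invasive, fx$native,
                              fx$stack$grid)$retained, 3L)
  # contamination is a hard error
  bad <- fx$models
  bad[[1]]$saw_invasive <- TRUE
  expect_error(stage2_filter(bad, fx$invasive, fx$native, fx$stack$grid),
               "contamination")
})

test_that("two-model arithmetic of the IHR cut", {
  stack <- make_test_stack(10, 10, seed = 5)
  inv <- dedup_to_cells(random_points(10, stack$grid, seed = 6,
                                      role = "invasive_presence"), stack)
  nat <- dedup_to_cells(random_points(10, stack$grid, seed = 7), stack)
  hi <- matrix(0, 10, 10); hi[as.matrix(inv[1:9, c("row", "col")])] <- 1
  hi[1, 10] <- 1   # keep non-constant off the validation cells
  lo <- matrix(0, 10, 10); lo[as.matrix(inv[1:5, c("row", "col")])] <- 1
  models <- list(model_stub("hi", "a", hi), model_stub("lo", "a", lo))
  res <- stage2_filter(models, inv, nat, stack$grid)
  expect_equal(res$retained, "hi")   # mean of {0.9, 0.5} = 0.7 cuts "lo"
})

test_that("the convergence sweep fixes mean PCC once and nests retained sets", {
  fx <- sel_fixture(n_models = 8, seed = 90)
  cfg <- selection_config()
  expect_length(cfg$pcc_grid, 51L)
  expect_equal(range(cfg$pcc_grid), c(0.5, 1.0))
  # similar maps: a shared base with progressively more flipped cells, plus
  # one deliberate outlier (the complement of the base)
  base <- random_binary_map(fx$stack, seed = 90)
  cells <- which(fx$stack$mask)
  for (i in 1:7) {
    m <- base
    set.seed(300 + i)
    fl <- sample(cells, 3 * i)
    m[fl] <- 1 - m[fl]
    fx$models[[i]] <- model_stub(sprintf("m%02d", i),
                                 c("a", "b")[1 + i %% 2], m)
  }
  fx$models[[8]] <- model_stub("m08", "b", 1 - base)
  sweep <- stage3_sweep(fx$models, cfg, fx$invasive, fx$native, fx$stack$grid)
  pcc_oracle <- mean_pairwise_pcc(lapply(fx$models, `[[`, "binary_map"))
  expect_equal(unname(sweep$mean_pcc), pcc_oracle)
  # the outlier holds the lowest mean PCC and is excluded first
  expect_equal(names(which.min(sweep$mean_pcc)), "m08")
  expect_false("m08" %in% sweep$retained[[length(sweep$retained)]])
  # nesting of retained sets and OPM cells along ascending thresholds
  for (i in seq_len(length(sweep$retained) - 1)) {
    expect_true(all(sweep$retained[[i + 1]] %in% sweep$retained[[i]]))
    expect_true(all(sweep$opms[[i]][sweep$opms[[i + 1]] == 1] == 1,
                    na.rm = TRUE))
  }
  # IHR, NHR, SCR are monotone non-increasing along the sweep
  expect_true(all(diff(sweep$series$ihr) <= 1e-12))
  expect_true(all(diff(sweep$series$nhr) <= 1e-12))
  expect_true(all(diff(sweep$series$scr) <= 1e-12))
  # identical maps survive to the top of the grid
  same <- lapply(1:3, function(i)
    model_stub(paste0("t", i), "a", fx$models[[1]]$binary_map))
  sw2 <- stage3_sweep(same, cfg, fx$invasive, fx$native, fx$stack$grid)
  expect_equal(max(sw2$series$threshold), 1.0)
  expect_equal(sw2$series$n_models[nrow(sw2$series)], 3L)
})

test_that("delta series equals pairwise differences", {
  df <- data.frame(threshold = c(0.5, 0.51, 0.52),
                   ihr = c(0.9, 0.9, 0.6), nhr = c(1, 0.8, 0.8),
                   scr = c(0.3, 0.2, 0.1))
  d <- delta_series(df)
  expect_equal(d$ihr, c(0, -0.3))
  expect_equal(d$nhr, c(-0.2, 0))
  expect_equal(d$threshold, c(0.51, 0.52))
  set.seed(3)
  r <- data.frame(threshold = seq(0.5, 0.6, 0.01), ihr = runif(11),
                  nhr = runif(11), scr = runif(11))
  expect_equal(delta_series(r)$scr, diff(r$scr))
  expect_error(delta_series(r[1, , drop = FALSE]), ">= 2")
})

test_that("threshold selection picks the value just before each marked shift", {
  # flat background with one large negative shift at position j selects j - 1
  thr <- seq(0.50, 0.70, by = 0.01)
  ihr <- rep(0.95, length(thr))
  ihr[thr >= 0.60] <- 0.70
  series <- data.frame(threshold = thr, ihr = ihr)
  sel <- select_opm_thresholds(series, selection_config())
  expect_equal(sel, 0.59)
  # all-zero deltas fall back to the median threshold with a warning
  flat <- data.frame(threshold = thr, ihr = rep(0.9, length(thr)))
  expect_warning(fb <- select_opm_thresholds(flat, selection_config()),
                 "fallback|median")
  expect_equal(fb, median(thr))
  # manual overrides are honoured verbatim
  ov <- selection_config(overrides = c(0.61, 0.52))
  expect_equal(select_opm_thresholds(series, ov), c(0.52, 0.61))
})

test_that("replaying the study's shift pattern selects 0.52, 0.61 and 0.74", {
  # series shaped like the published delta plot: isolated drops entering
  # 0.53 and 0.62, and a decrease run starting at 0.75 that deepens at 0.79
  thr <- seq(0.50, 0.79, by = 0.01)
  ihr <- rep(0.97, length(thr))
  drop_at <- function(v, at, amount) { v[thr >= at] <- v[thr >= at] - amount; v }
  ihr <- drop_at(ihr, 0.53, 0.06)
  ihr <- drop_at(ihr, 0.62, 0.07)
  for (t in seq(0.75, 0.78, 0.01)) ihr <- drop_at(ihr, t, 0.01)
  ihr <- drop_at(ihr, 0.79, 0.08)
  series <- data.frame(threshold = thr, ihr = ihr)
  sel <- select_opm_thresholds(series, selection_config())
  expect_equal(sel, c(0.52, 0.61, 0.74))
  # the last threshold of the range is never selected
  expect_false(max(thr) %in% sel)
})

test_that("stage results report per-algorithm counts", {
  fx <- sel_fixture(n_models = 6, seed = 120)
  res <- stage1_filter(fx$models, tss_min = 0, fx$invasive, fx$native,
                       fx$stack$grid)
  counts <- res$per_algorithm_counts
  expect_equal(sum(counts), 6)
  expect_setequal(names(counts), c("a", "b"))
})
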