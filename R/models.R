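#' Modelling design
#'
#' The full factorial design: every combination of algorithm, presence
#' partition run, and pseudo-absence subset yields one fitted model, for
#' `length(algorithms) * n_runs * k` models in total (a 10-algorithm battery
#' with 5 runs and 5 subsets gives 250).
#'
#' @param algorithms Character vector of registered learner ids.
#' @param n_runs Number of independent 75/25 presence partitions.
#' @param train_fraction Fraction of presence cells used for training.
#' @param pa_subsets Number of pseudo-absence subsets k.
#' @param seed Integer seed; run- and model-level sub-seeds derive from it.
#' @return An object of class `modeling_design`.
#' @export
modeling_design <- function(algorithms = c("glm", "gam", "gbm", "maxlike"),
                            n_runs = 5, train_fraction = 0.75,
                            pa_subsets = 5, seed = 1L) {
  stopifnot(length(algorithms) >= 1, n_runs >= 1,
            train_fraction > 0, train_fraction < 1, pa_subsets >= 1)
  unknown <- setdiff(algorithms, names(learner_registry()))
  if (length(unknown))
    stop("unregistered learner(s): ", paste(unknown, collapse = ", "))
  structure(list(algorithms = algorithms, n_runs = as.integer(n_runs),
                 train_fraction = train_fraction,
                 pa_subsets = as.integer(pa_subsets), seed = as.integer(seed)),
            class = "modeling_design")
}

#' Total models in a design
#'
#' @param design A [modeling_design()].
#' @return `length(algorithms) * n_runs * pa_subsets`.
#' @export
design_size <- function(design) {
  length(design$algorithms) * design$n_runs * design$pa_subsets
}

#' Partition presences into train/test splits
#'
#' `n_runs` independent seeded random partitions of the presence cells;
#' `round(train_fraction * n)` cells train, the remainder evaluate. Each run
#' uses sub-seed `seed + run`.
#'
#' @param native Deduplicated native-presence `occurrence_set` (>= 8 records
#'   so both parts are non-empty).
#' @param design A [modeling_design()].
#' @return List of `n_runs` lists with integer row indices `train`, `test`.
#' @export
partition_presences <- function(native, design) {
  n <- nrow(native)
  if (n < 8) stop("too few presences to partition (need >= 8, got ", n, ")")
  n_train <- round(design$train_fraction * n)
  lapply(seq_len(design$n_runs), function(run) {
    set.seed(design$seed + run)
    tr <- sort(sample.int(n, n_train))
    list(train = tr, test = setdiff(seq_len(n), tr))
  })
}

#' Assemble a labelled training table
#'
#' One row per point: label 1 for presences, 0 for pseudo-absences; features
#' are the (pruned) layer values at the containing cell.
#'
#' @param presences,pa_points Deduplicated `occurrence_set`s on analyzable
#'   cells.
#' @param stack The pruned [layer_stack()].
#' @return data.frame with column `label` followed by one column per layer.
#' @export
assemble_training_table <- function(presences, pa_points, stack) {
  pts <- rbind(as.data.frame(presences)[, c("x", "y")],
               as.data.frame(pa_points)[, c("x", "y")])
  ps <- occurrence_set(pts$x, pts$y, "native_presence")
  feats <- lapply(stack$layers, extract_cell_values,
                  points = ps, grid = stack$grid)
  tab <- data.frame(label = c(rep(1, nrow(presences)), rep(0, nrow(pa_points))),
                    feats, check.names = TRUE)
  if (anyNA(tab)) stop("point(s) on nodata cells; clean inputs first")
  tab
}

# --- learner registry -------------------------------------------------------

.suscept_learners <- new.env(parent = emptyenv())

#' Register a suitability learner
#'
#' A learner is any function `function(table, seed)` returning a predictor:
#' `function(newdata) -> scores in [0, 1]`, where `table` is a training table
#' from [assemble_training_table()] and `newdata` a data.frame of the same
#' feature columns. Registered learners are addressed by id in
#' [modeling_design()].
#'
#' @param id Learner identifier.
#' @param fit_fun The fitting function.
#' @export
register_learner <- function(id, fit_fun) {
  stopifnot(is.character(id), length(id) == 1, is.function(fit_fun))
  assign(id, fit_fun, envir = .suscept_learners)
  invisible(id)
}

learner_registry <- function() as.list(.suscept_learners)

#' List registered learner ids
#' @return Character vector.
#' @export
list_learners <- function() sort(names(learner_registry()))

# Built-in learners, one per family the ensemble literature leans on.
# Each returns a closure predicting probabilities over feature rows.

learner_glm <- function(table, seed) {
  # additive polynomial response (linear + quadratic), the customary GLM
  # formulation for unimodal environmental responses
  feats <- setdiff(names(table), "label")
  rhs <- paste(c(feats, sprintf("I(%s^2)", feats)), collapse = " + ")
  fit <- suppressWarnings(
    stats::glm(stats::as.formula(paste("label ~", rhs)), data = table,
               family = stats::binomial()))
  function(newdata) {
    p <- suppressWarnings(
      stats::predict(fit, newdata = newdata, type = "response"))
    pmin(pmax(as.numeric(p), 0), 1)
  }
}

learner_gam <- function(table, seed) {
  feats <- setdiff(names(table), "label")
  k <- max(4, min(8, floor(nrow(table) / 20)))
  rhs <- paste(sprintf("s(%s, k = %d)", feats, k), collapse = " + ")
  fit <- mgcv::gam(stats::as.formula(paste("label ~", rhs)),
                   data = table, family = stats::binomial(), method = "REML")
  function(newdata) {
    p <- mgcv::predict.gam(fit, newdata = newdata, type = "response")
    pmin(pmax(as.numeric(p), 0), 1)
  }
}

learner_gbm <- function(table, seed) {
  feats <- setdiff(names(table), "label")
  x <- as.matrix(table[, feats, drop = FALSE])
  dtrain <- xgboost::xgb.DMatrix(x, label = table$label)
  fit <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = 3, eta = 0.1,
                  nthread = 1, seed = seed),
    data = dtrain, nrounds = 100, verbose = 0)
  function(newdata) {
    nd <- xgboost::xgb.DMatrix(as.matrix(newdata[, feats, drop = FALSE]))
    p <- stats::predict(fit, nd)
    pmin(pmax(as.numeric(p), 0), 1)
  }
}

# maxent-flavoured learner: lasso-penalized logistic on linear + quadratic
# features (the hinge-free core of the maxnet feature space)
learner_maxlike <- function(table, seed) {
  feats <- setdiff(names(table), "label")
  expand <- function(df) {
    m <- as.matrix(df[, feats, drop = FALSE])
    cbind(m, m^2)
  }
  x <- expand(table)
  set.seed(seed)
  cv <- glmnet::cv.glmnet(x, table$label, family = "binomial", alpha = 1,
                          nfolds = 5)
  function(newdata) {
    p <- stats::predict(cv, newx = expand(newdata), s = "lambda.min",
                        type = "response")
    pmin(pmax(as.numeric(p), 0), 1)
  }
}

learner_rf <- function(table, seed) {
  tab <- table
  tab$label <- factor(tab$label, levels = c(0, 1))
  fit <- ranger::ranger(label ~ ., data = tab, probability = TRUE,
                        num.trees = 300, seed = seed, num.threads = 1)
  function(newdata) {
    p <- stats::predict(fit, data = newdata, num.threads = 1)$predictions[, "1"]
    pmin(pmax(as.numeric(p), 0), 1)
  }
}

# rectangular surface-range envelope: score 1 inside the presence quantile
# box, 0 outside
learner_sre <- function(table, seed, quantile_trim = 0.025) {
  feats <- setdiff(names(table), "label")
  pres <- table[table$label == 1, feats, drop = FALSE]
  lo <- vapply(pres, stats::quantile, numeric(1), probs = quantile_trim)
  hi <- vapply(pres, stats::quantile, numeric(1), probs = 1 - quantile_trim)
  function(newdata) {
    inside <- rep(TRUE, nrow(newdata))
    for (i in seq_along(feats)) {
      v <- newdata[[feats[i]]]
      inside <- inside & v >= lo[i] & v <= hi[i]
    }
    as.numeric(inside)
  }
}

register_builtin_learners <- function() {
  register_learner("glm", learner_glm)
  register_learner("gam", learner_gam)
  register_learner("gbm", learner_gbm)
  register_learner("maxlike", learner_maxlike)
  register_learner("rf", learner_rf)
  register_learner("sre", learner_sre)
}

.onLoad <- function(libname, pkgname) register_builtin_learners()

# --- fitting and prediction -------------------------------------------------

#' Fit one learner and predict suitability over the grid
#'
#' Trains the learner on a labelled table and scores every analyzable cell,
#' returning a continuous suitability map in [0, 1]. Deterministic for a
#' fixed seed.
#'
#' @param table Training table from [assemble_training_table()] with both
#'   classes present.
#' @param stack The pruned [layer_stack()].
#' @param algo_id Registered learner id.
#' @param seed Integer seed handed to the learner.
#' @return Matrix of per-cell scores (`NA` outside analyzable cells).
#' @export
fit_and_predict <- function(table, stack, algo_id, seed = 1L) {
  fit_fun <- learner_registry()[[algo_id]]
  if (is.null(fit_fun)) stop("unregistered learner: ", algo_id)
  if (length(unique(table$label)) < 2)
    stop("training table holds a single class")
  set.seed(seed)
  predictor <- fit_fun(table, seed)
  mask <- stack$mask
  newdata <- as.data.frame(lapply(stack$layers, function(m) m[mask]))
  scores <- predictor(newdata)
  if (any(!is.finite(scores)))
    stop("non-finite predictions from learner ", algo_id)
  out <- matrix(NA_real_, stack$grid$n_rows, stack$grid$n_cols)
  out[mask] <- scores
  out
}

#' Binarize a suitability map at the max-sensitivity+specificity threshold
#'
#' Scans candidate cutpoints (the unique evaluation scores plus midpoints
#' between consecutive ones) and picks the threshold maximizing
#' `sensitivity + specificity` on the evaluation data; ties resolve to the
#' smallest such threshold. Cells scoring at or above the threshold become 1.
#'
#' @param continuous_map Score matrix from [fit_and_predict()].
#' @param presence_scores Scores at held-out presence cells.
#' @param absence_scores Scores at held-out pseudo-absence cells.
#' @return List with `threshold`, `binary_map`, `sensitivity`, `specificity`,
#'   `tss` (all at the chosen threshold).
#' @export
binarize_max_ss <- function(continuous_map, presence_scores, absence_scores) {
  if (length(presence_scores) == 0 || length(absence_scores) == 0)
    stop("both evaluation classes must be non-empty")
  all_scores <- sort(unique(c(presence_scores, absence_scores)))
  if (length(all_scores) == 1) {
    warning("all evaluation scores equal; degenerate threshold")
    cands <- all_scores
  } else {
    mids <- (all_scores[-1] + all_scores[-length(all_scores)]) / 2
    cands <- sort(unique(c(all_scores, mids)))
  }
  best <- -Inf; thr <- cands[1]; best_sens <- NA; best_spec <- NA
  for (t in cands) {
    sens <- mean(presence_scores >= t)
    spec <- mean(absence_scores < t)
    if (sens + spec > best + 1e-12) {
      best <- sens + spec; thr <- t; best_sens <- sens; best_spec <- spec
    }
  }
  list(threshold = thr,
       binary_map = (continuous_map >= thr) * 1,
       sensitivity = best_sens, specificity = best_spec,
       tss = best_sens + best_spec - 1)
}
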