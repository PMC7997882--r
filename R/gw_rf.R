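#' Random forest hyperparameters
#'
#' Container for the regression-forest settings used by the global and
#' geographically weighted forests. Defaults are standard regression-forest
#' conventions: bootstrap of n with replacement, no depth limit, terminal
#' node size 5. `mtry = NULL` uses `max(floor(p / 3), 1)` at fit time. The
#' reference configuration for a full-scale county analysis is
#' `ntree = 2950, mtry = 4` with a 284-neighbor calibration set; the
#' package's examples use smaller forests that preserve all tested
#' properties.
#'
#' @param ntree Trees per forest (>= 1).
#' @param mtry Predictors sampled per split (`NULL` = regression default).
#' @param min_node_size Minimum terminal node size.
#' @param sample_fraction Bootstrap sample fraction (with replacement).
#' @param seed Integer seed.
#' @return An `rf_params` list.
#' @export
rf_params <- function(ntree = 500, mtry = NULL, min_node_size = 5,
                      sample_fraction = 1, seed = 1) {
  if (ntree < 1) abort_config("ntree must be >= 1.")
  if (!is.null(mtry) && mtry < 1) abort_config("mtry must be >= 1.")
  if (sample_fraction <= 0 || sample_fraction > 1) {
    abort_config("sample_fraction must lie in (0, 1].")
  }
  structure(list(ntree = as.integer(ntree), mtry = mtry,
                 min_node_size = as.integer(min_node_size),
                 sample_fraction = sample_fraction, seed = as.integer(seed)),
            class = "rf_params")
}

# Single seeded regression forest with both importance measures.
# %IncMSE is reported in the unscaled relative form:
# 100 * (mean per-tree OOB MSE increase under permutation) / forest OOB MSE.
# The variance-scaled variant (raw increase / its standard error) is kept
# alongside. IncNodePurity is the node-SSE decrease from splits on the
# variable, averaged over trees.
fit_rf_engine <- function(X, y, params) {
  n <- nrow(X)
  p <- ncol(X)
  mtry <- min(params$mtry %||% max(floor(p / 3), 1), p)
  if (var(y) == 0) {
    warn("Constant outcome: forest is degenerate; importances set to 0.")
    imp <- tibble::tibble(predictor = colnames(X), incmse_pct = 0,
                          incmse_scaled = 0, inc_node_purity = 0)
    return(list(forest = NULL, oob_mse = 0, oob_r2 = NA_real_,
                importance = imp, oob_pred = rep(y[1], n)))
  }
  set.seed(params$seed)
  rf <- randomForest::randomForest(
    x = X, y = y, ntree = params$ntree, mtry = mtry,
    nodesize = params$min_node_size,
    sampsize = ceiling(params$sample_fraction * n), replace = TRUE,
    importance = TRUE)
  oob_mse <- mean((rf$predicted - y)^2, na.rm = TRUE)
  imp_raw <- rf$importance[, "%IncMSE"]
  imp_sd <- rf$importanceSD
  imp <- tibble::tibble(
    predictor = colnames(X),
    incmse_pct = 100 * imp_raw / oob_mse,
    incmse_scaled = ifelse(imp_sd > 0, imp_raw / imp_sd, 0),
    inc_node_purity = rf$importance[, "IncNodePurity"])
  list(forest = rf, oob_mse = oob_mse, oob_r2 = 1 - oob_mse / var(y),
       importance = imp, oob_pred = rf$predicted)
}

#' Fit a global random forest
#'
#' Bootstrap regression forest on the whole areal table, with out-of-bag
#' (OOB) error, OOB pseudo-R-squared, and two per-predictor importance
#' measures: permutation %IncMSE (percent increase in OOB mean squared error
#' when the predictor is permuted within each tree's OOB set, relative to
#' the forest OOB MSE) and IncNodePurity (node sum-of-squares decrease from
#' splits on the predictor, averaged over trees).
#'
#' @param frame An [as_area_frame()].
#' @param params An [rf_params()].
#' @return A `global_rf` object with elements `forest`, `oob_mse`, `oob_r2`,
#'   `importance` (tibble), `params`.
#' @export
fit_global_rf <- function(frame, params = rf_params()) {
  X <- area_predictors(frame)
  y <- area_outcome(frame)
  if (nrow(X) < 10) abort_config("Global forest requires n >= 10.")
  eng <- fit_rf_engine(X, y, params)
  structure(c(eng, list(params = params, frame = frame)),
            class = "global_rf")
}

#' @export
print.global_rf <- function(x, ...) {
  cat(sprintf("Global random forest: ntree = %d, OOB MSE = %.4f, OOB R2 = %.3f\n",
              x$params$ntree, x$oob_mse, x$oob_r2))
  print(as.data.frame(x$importance), row.names = FALSE, digits = 4)
  invisible(x)
}

# Rank a location's importances descending; exact ties resolved by input
# column order (deterministic).
rank_importance <- function(v) {
  rank(-v, ties.method = "first")
}

# Pure early-stopping rule shared with random_grid_search: given the running
# sequence of CV scores (lower is better), returns the 1-based index of the
# last draw evaluated before stopping, or length(scores) if never triggered.
# A draw "improves" when it lowers the best score so far by more than
# `tolerance` relative; `rounds` consecutive non-improving draws stop the
# search.
early_stop_index <- function(scores, tolerance, rounds) {
  best <- scores[1]
  stale <- 0L
  for (i in seq_along(scores)[-1]) {
    rel_gain <- (best - scores[i]) / abs(best)
    if (is.finite(rel_gain) && rel_gain > tolerance) {
      best <- min(best, scores[i])
      stale <- 0L
    } else {
      best <- min(best, scores[i])
      stale <- stale + 1L
      if (stale >= rounds) return(i)
    }
  }
  length(scores)
}

#' Random grid search for forest hyperparameters
#'
#' Samples hyperparameter combinations without replacement from a candidate
#' grid and scores each by mean K-fold cross-validated MSE. The search stops
#' early when the best score has failed to improve by more than
#' `stopping_tolerance` (relative) for `stopping_rounds` consecutive draws —
#' the 0.001 / 2 defaults mirror the tuning convention the package's
#' reference configuration was derived with.
#'
#' @param frame An [as_area_frame()].
#' @param grid A data frame of candidate rows with any of the columns
#'   `ntree`, `mtry`, `min_node_size`, `sample_fraction`.
#' @param k_folds Cross-validation folds (>= 2; default 5).
#' @param n_draws Combinations to sample (default: all; capped at the grid
#'   size with a warning).
#' @param stopping_tolerance Relative improvement threshold (default 0.001).
#' @param stopping_rounds Consecutive non-improving draws tolerated
#'   (default 2).
#' @param seed Integer seed for the draw order, fold assignment and forests.
#' @return List with `best` (an [rf_params()]), `trace` (tibble of evaluated
#'   combinations with `cv_mse`, in evaluation order) and `stopped_early`.
#' @export
random_grid_search <- function(frame, grid, k_folds = 5, n_draws = NULL,
                               stopping_tolerance = 0.001,
                               stopping_rounds = 2, seed = 1) {
  if (nrow(grid) == 0) abort_config("Hyperparameter grid is empty.")
  if (k_folds < 2) abort_config("k_folds must be >= 2.")
  n_draws <- n_draws %||% nrow(grid)
  if (n_draws > nrow(grid)) {
    warn(sprintf("n_draws (%d) exceeds grid size (%d); capped.",
                 n_draws, nrow(grid)))
    n_draws <- nrow(grid)
  }
  X <- area_predictors(frame)
  y <- area_outcome(frame)
  n <- nrow(X)
  folds <- kfold_splits(n, k_folds, seed = hash_seed(seed, 2))
  set.seed(seed)
  order_idx <- sample.int(nrow(grid), n_draws)
  cv_mse_one <- function(par_row, draw) {
    params <- rf_params(
      ntree = par_row$ntree %||% 500,
      mtry = par_row$mtry,
      min_node_size = par_row$min_node_size %||% 5,
      sample_fraction = par_row$sample_fraction %||% 1,
      seed = hash_seed(seed, 100 + draw))
    mses <- vapply(seq_len(k_folds), function(f) {
      tr <- folds != f
      mtry <- min(params$mtry %||% max(floor(ncol(X) / 3), 1), ncol(X))
      set.seed(hash_seed(params$seed, f))
      rf <- randomForest::randomForest(
        x = X[tr, , drop = FALSE], y = y[tr], ntree = params$ntree,
        mtry = mtry, nodesize = params$min_node_size,
        sampsize = ceiling(params$sample_fraction * sum(tr)), replace = TRUE)
      mean((predict(rf, X[!tr, , drop = FALSE]) - y[!tr])^2)
    }, numeric(1))
    mean(mses)
  }
  scores <- numeric(0)
  rows <- list()
  stopped_early <- FALSE
  best <- Inf
  stale <- 0L
  for (d in seq_len(n_draws)) {
    par_row <- as.list(grid[order_idx[d], , drop = FALSE])
    score <- cv_mse_one(par_row, d)
    scores <- c(scores, score)
    rows[[d]] <- tibble::as_tibble(c(par_row, list(cv_mse = score)))
    if (d > 1) {
      rel_gain <- (best - score) / abs(best)
      if (is.finite(rel_gain) && rel_gain > stopping_tolerance) {
        stale <- 0L
      } else {
        stale <- stale + 1L
      }
    }
    best <- min(best, score)
    if (stale >= stopping_rounds) {
      stopped_early <- d < n_draws
      break
    }
  }
  trace <- dplyr::bind_rows(rows)
  best_row <- as.list(trace[which.min(trace$cv_mse), , drop = FALSE])
  list(best = rf_params(ntree = best_row$ntree %||% 500,
                        mtry = best_row$mtry,
                        min_node_size = best_row$min_node_size %||% 5,
                        sample_fraction = best_row$sample_fraction %||% 1,
                        seed = seed),
       trace = trace, stopped_early = stopped_early)
}

#' Partial dependence of a forest prediction on one feature
#'
#' `PDP(v)` is the mean prediction over the training rows with the chosen
#' feature fixed at `v`; the grid defaults to evenly spaced quantiles of the
#' feature's training distribution (5% to 95%).
#'
#' @param fit A [fit_global_rf()] result.
#' @param feature Predictor name.
#' @param grid_points Number of quantile grid points (default 20), or pass
#'   `grid` directly.
#' @param grid Optional explicit numeric grid.
#' @return A tibble with `feature`, `value`, `pdp`.
#' @export
partial_dependence <- function(fit, feature, grid_points = 20, grid = NULL) {
  X <- area_predictors(fit$frame)
  if (!feature %in% colnames(X)) {
    abort_config(paste0("Unknown feature: ", feature))
  }
  if (is.null(grid)) {
    grid <- unique(quantile(X[, feature],
                            probs = seq(0.05, 0.95,
                                        length.out = grid_points)))
  }
  pdp <- vapply(grid, function(v) {
    Xv <- X
    Xv[, feature] <- v
    if (is.null(fit$forest)) return(mean(fit$oob_pred))
    mean(predict(fit$forest, Xv))
  }, numeric(1))
  tibble::tibble(feature = feature, value = as.numeric(grid), pdp = pdp)
}

#' Fit a geographically weighted random forest
#'
#' Trains one regression forest per location on that location's calibration
#' set — the focal unit plus its `k_neighbors - 1` nearest neighbors (an
#' adaptive bandwidth defining membership, not sample weights) — and records
#' local OOB MSE, local pseudo-R-squared (`1 - OOB MSE / var(local y)`), and
#' per-predictor local %IncMSE and IncNodePurity. A global companion forest
#' with the same hyperparameters supports blended prediction and global
#' comparisons. Per-location seeds are derived deterministically from
#' `(seed, i)` so results are independent of evaluation order.
#'
#' @param frame An [as_area_frame()].
#' @param k_neighbors Local calibration-set size, `>= max(10, p + 2)`. The
#'   full-scale county reference configuration is 284.
#' @param params An [rf_params()] (its `seed` is superseded by `seed` here).
#' @param seed Integer master seed.
#' @param keep_forests Keep each local forest (needed for local prediction).
#' @param force_global_seed Use the master seed for every local forest
#'   instead of per-location streams (used to verify the `k = n`
#'   definitional limit against the global forest).
#' @return A `gwrf_fit` object with `local` (tibble: `id`, `oob_mse`,
#'   `pseudo_r2`, `incmse_<var>`, `nodepurity_<var>`, `rank_<var>`),
#'   `global` (the companion [fit_global_rf()]), and metadata.
#' @export
fit_gwrf <- function(frame, k_neighbors, params = rf_params(), seed = 1,
                     keep_forests = TRUE, force_global_seed = FALSE) {
  X <- area_predictors(frame)
  y <- area_outcome(frame)
  n <- nrow(X)
  p <- ncol(X)
  if (k_neighbors < max(10, p + 2) || k_neighbors > n) {
    abort_config(sprintf("k_neighbors must lie in [%d, %d].",
                         max(10, p + 2), n))
  }
  coords <- area_coords(frame)
  D <- pairwise_distances(coords)
  global <- fit_global_rf(frame, rf_params(ntree = params$ntree,
                                           mtry = params$mtry,
                                           min_node_size = params$min_node_size,
                                           sample_fraction = params$sample_fraction,
                                           seed = seed))
  oob_mse <- numeric(n)
  pseudo_r2 <- numeric(n)
  incmse <- matrix(NA_real_, n, p, dimnames = list(NULL, colnames(X)))
  nodepurity <- matrix(NA_real_, n, p, dimnames = list(NULL, colnames(X)))
  forests <- if (keep_forests) vector("list", n) else NULL
  undefined <- logical(n)
  for (i in seq_len(n)) {
    ord <- order(D[i, -i], method = "radix")
    others <- seq_len(n)[-i]
    idx <- sort(c(i, others[ord[seq_len(k_neighbors - 1)]]))
    local_seed <- if (force_global_seed) seed else hash_seed(seed, i)
    local_params <- rf_params(ntree = params$ntree, mtry = params$mtry,
                              min_node_size = params$min_node_size,
                              sample_fraction = params$sample_fraction,
                              seed = local_seed)
    if (var(y[idx]) == 0) {
      undefined[i] <- TRUE
      oob_mse[i] <- 0
      pseudo_r2[i] <- NA_real_
      incmse[i, ] <- 0
      nodepurity[i, ] <- 0
      next
    }
    eng <- fit_rf_engine(X[idx, , drop = FALSE], y[idx], local_params)
    oob_mse[i] <- eng$oob_mse
    pseudo_r2[i] <- 1 - eng$oob_mse / var(y[idx])
    incmse[i, ] <- eng$importance$incmse_pct
    nodepurity[i, ] <- eng$importance$inc_node_purity
    if (keep_forests) forests[[i]] <- eng$forest
  }
  ranks <- t(apply(incmse, 1, function(v) {
    if (any(is.na(v))) return(rep(NA_integer_, p))
    rank_importance(v)
  }))
  local <- tibble::tibble(id = area_ids(frame), oob_mse = oob_mse,
                          pseudo_r2 = pseudo_r2, undefined = undefined)
  for (j in seq_len(p)) local[[paste0("incmse_", colnames(X)[j])]] <- incmse[, j]
  for (j in seq_len(p)) local[[paste0("nodepurity_", colnames(X)[j])]] <- nodepurity[, j]
  for (j in seq_len(p)) local[[paste0("rank_", colnames(X)[j])]] <- ranks[, j]
  structure(list(local = local, incmse = incmse, nodepurity = nodepurity,
                 ranks = ranks, undefined = undefined, global = global,
                 forests = forests, k_neighbors = as.integer(k_neighbors),
                 params = params, seed = seed, frame = frame),
            class = "gwrf_fit")
}

#' Rank locations' predictors by local importance
#'
#' Per location, predictors are ranked by local %IncMSE (descending, ties to
#' the earlier column); the summary reports, for each predictor, the percent
#' of locations where it holds rank 1, 2 and 3. Locations with undefined
#' importance are excluded and counted.
#'
#' @param fit A [fit_gwrf()] result.
#' @return A tibble with `predictor`, `pct_rank1`, `pct_rank2`, `pct_rank3`,
#'   plus attribute `n_excluded`.
#' @export
local_importance_ranking <- function(fit) {
  stopifnot(inherits(fit, "gwrf_fit"))
  ok <- !fit$undefined
  ranks <- fit$ranks[ok, , drop = FALSE]
  n_ok <- nrow(ranks)
  preds <- colnames(fit$incmse)
  out <- purrr::map_dfr(seq_along(preds), function(j) {
    tibble::tibble(
      predictor = preds[j],
      pct_rank1 = 100 * sum(ranks[, j] == 1) / n_ok,
      pct_rank2 = 100 * sum(ranks[, j] == 2) / n_ok,
      pct_rank3 = 100 * sum(ranks[, j] == 3) / n_ok)
  })
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Summary of local importance surfaces
#'
#' Min / Max / Mean / Std of each predictor's local %IncMSE surface plus the
#' local OOB MSE and pseudo-R-squared rows — the compact display
#' conventional for a GW-RF next to its global companion.
#'
#' @param fit A [fit_gwrf()] result.
#' @return A tibble with `quantity`, `global`, `min`, `max`, `mean`, `sd`.
#' @export
gwrf_summary <- function(fit) {
  stopifnot(inherits(fit, "gwrf_fit"))
  ok <- !fit$undefined
  preds <- colnames(fit$incmse)
  g_imp <- fit$global$importance
  rows <- purrr::map_dfr(seq_along(preds), function(j) {
    v <- fit$incmse[ok, j]
    tibble::tibble(quantity = paste0("incmse_", preds[j]),
                   global = g_imp$incmse_pct[j],
                   min = min(v), max = max(v), mean = mean(v), sd = sd(v))
  })
  mse <- fit$local$oob_mse[ok]
  r2 <- fit$local$pseudo_r2[ok]
  dplyr::bind_rows(
    rows,
    tibble::tibble(quantity = "oob_mse", global = fit$global$oob_mse,
                   min = min(mse), max = max(mse), mean = mean(mse),
                   sd = sd(mse)),
    tibble::tibble(quantity = "pseudo_r2", global = fit$global$oob_r2,
                   min = min(r2, na.rm = TRUE), max = max(r2, na.rm = TRUE),
                   mean = mean(r2, na.rm = TRUE), sd = sd(r2, na.rm = TRUE)))
}

#' Predict from a GW-RF fit
#'
#' The local prediction at a new point is the prediction of the forest whose
#' calibration location is nearest (distance ties broken by lower id); the
#' returned value blends it with the global companion forest:
#' `local_weight * local + (1 - local_weight) * global`. The default
#' `local_weight = 1` (purely local) is a documented package choice.
#'
#' @param object A [fit_gwrf()] result with `keep_forests = TRUE`.
#' @param newdata Data frame with the training coordinate and predictor
#'   columns.
#' @param local_weight Blend weight in `[0, 1]`.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.gwrf_fit <- function(object, newdata, local_weight = 1, ...) {
  if (local_weight < 0 || local_weight > 1) {
    abort_config("local_weight must lie in [0, 1].")
  }
  roles <- gw_roles(object$frame)
  miss <- setdiff(c(roles$coords, roles$predictors), names(newdata))
  if (length(miss) > 0) {
    abort_schema(paste0("newdata lacks column(s): ",
                        paste(miss, collapse = ", ")))
  }
  X_new <- as.matrix(newdata[, roles$predictors])
  colnames(X_new) <- roles$predictors
  global_pred <- as.numeric(predict(object$global$forest, X_new))
  if (local_weight == 0) return(global_pred)
  if (is.null(object$forests)) {
    abort_config("Fit was built with keep_forests = FALSE; local predictions unavailable.")
  }
  coords_tr <- area_coords(object$frame)
  new_coords <- as.matrix(newdata[, roles$coords])
  local_pred <- vapply(seq_len(nrow(X_new)), function(i) {
    d <- sqrt((coords_tr[, 1] - new_coords[i, 1])^2 +
                (coords_tr[, 2] - new_coords[i, 2])^2)
    nearest <- which(d == min(d))[1]
    as.numeric(predict(object$forests[[nearest]],
                       X_new[i, , drop = FALSE]))
  }, numeric(1))
  local_weight * local_pred + (1 - local_weight) * global_pred
}

#' @describeIn fit_gwrf Long per-location importance table (one row per
#'   location x predictor).
#' @param x A `gwrf_fit`.
#' @param ... Unused.
#' @export
tidy.gwrf_fit <- function(x, ...) {
  ids <- x$local$id
  preds <- colnames(x$incmse)
  purrr::map_dfr(seq_along(preds), function(j) {
    tibble::tibble(id = ids, predictor = preds[j],
                   incmse_pct = x$incmse[, j],
                   inc_node_purity = x$nodepurity[, j],
                   rank = x$ranks[, j])
  })
}

#' @describeIn fit_gwrf One-row summary (mean/range of local pseudo-R2,
#'   mean local OOB MSE, global OOB R2, settings).
#' @export
glance.gwrf_fit <- function(x, ...) {
  ok <- !x$undefined
  r2 <- x$local$pseudo_r2[ok]
  tibble::tibble(mean_pseudo_r2 = mean(r2, na.rm = TRUE),
                 min_pseudo_r2 = min(r2, na.rm = TRUE),
                 max_pseudo_r2 = max(r2, na.rm = TRUE),
                 mean_oob_mse = mean(x$local$oob_mse[ok]),
                 global_oob_r2 = x$global$oob_r2,
                 k_neighbors = x$k_neighbors,
                 ntree = x$params$ntree, n = nrow(x$local))
}

#' @export
print.gwrf_fit <- function(x, ...) {
  g <- glance(x)
  cat("Geographically weighted random forest fit\n")
  cat(sprintf("  n = %d, k = %d, ntree = %d\n", g$n, g$k_neighbors, g$ntree))
  cat(sprintf("  local pseudo-R2: mean %.3f (range %.3f to %.3f)\n",
              g$mean_pseudo_r2, g$min_pseudo_r2, g$max_pseudo_r2))
  invisible(x)
}
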