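#' Random K-fold assignment
#'
#' Partitions `1..n` into `k` folds whose sizes differ by at most one.
#'
#' @param n Number of records.
#' @param k Number of folds, `2 <= k <= n`.
#' @param seed Integer seed.
#' @return Integer vector of fold labels in `1..k`.
#' @export
kfold_splits <- function(n, k, seed = 1) {
  if (k < 2 || k > n) abort_config(sprintf("k must lie in [2, %d].", n))
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

#' Random train/test split of an areal frame
#'
#' Disjoint, exhaustive, seeded split. The full-scale county reference
#' configuration is n = 3108 split into 2484 training and 624 test units.
#'
#' @param frame An [as_area_frame()] (or tibble).
#' @param n_test Test-set size, `0 < n_test < n`.
#' @param seed Integer seed.
#' @return List with `train` and `test` frames and the logical `test_mask`.
#' @export
train_test_split <- function(frame, n_test, seed = 1) {
  n <- nrow(frame)
  if (n_test <= 0 || n_test >= n) {
    abort_config(sprintf("n_test must lie in (0, %d).", n))
  }
  set.seed(seed)
  test_idx <- sort(sample.int(n, n_test))
  mask <- seq_len(n) %in% test_idx
  list(train = frame[!mask, , drop = FALSE],
       test = frame[mask, , drop = FALSE],
       test_mask = mask, seed = seed)
}

#' Prediction accuracy scores
#'
#' `RMSE = sqrt(mean((observed - predicted)^2))`. Two explained-variance
#' measures are reported: `r2` is the squared Pearson correlation of
#' observed and predicted (the 1:1-plot convention, invariant to a constant
#' offset) and `r2_ss = 1 - SSE/SST` (the strict skill form). Both are kept
#' because the two conventions genuinely differ for biased predictions.
#'
#' @param observed,predicted Equal-length numeric vectors (length >= 2).
#' @return One-row tibble: `rmse`, `r2`, `r2_ss`, `n`.
#' @export
score_predictions <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2) {
    abort_validation("observed and predicted must have equal length >= 2.")
  }
  if (var(observed) == 0) {
    abort_degenerate("Zero observed variance: R2 undefined.")
  }
  err <- observed - predicted
  tibble::tibble(
    rmse = sqrt(mean(err^2)),
    r2 = if (var(predicted) == 0) 0 else cor(observed, predicted)^2,
    r2_ss = 1 - sum(err^2) / sum((observed - mean(observed))^2),
    n = length(observed))
}

# Fit one model spec on a training frame and predict a test frame.
fit_and_predict <- function(model, train, test, control, seed) {
  roles <- gw_roles(train)
  fml <- stats::as.formula(paste(
    roles$outcome, "~", paste(roles$predictors, collapse = " + ")))
  switch(
    model,
    ols = {
      fit <- lm(fml, data = train)
      as.numeric(predict(fit, newdata = test))
    },
    rf = {
      params <- control$rf_params %||% rf_params()
      params$seed <- hash_seed(seed, 11)
      fit <- fit_global_rf(train, params)
      as.numeric(predict(fit$forest, as.matrix(test[, roles$predictors])))
    },
    gw_ols = {
      kernel <- control$gwols_kernel %||%
        kernel_spec("bisquare", adaptive = TRUE, bandwidth = NULL)
      fit <- fit_gwols(train, kernel)
      predict(fit, test)
    },
    gw_rf = {
      params <- control$rf_params %||% rf_params()
      k <- control$gwrf_k %||% max(10, length(roles$predictors) + 2,
                                   round(nrow(train) / 5))
      fit <- fit_gwrf(train, k_neighbors = k, params = params,
                      seed = hash_seed(seed, 13))
      predict(fit, test, local_weight = control$gwrf_local_weight %||% 1)
    },
    abort_config(paste0("Unknown model: ", model))
  )
}

#' Compare global and geographically weighted models on held-out data
#'
#' Fits each requested model on the training portion and scores it on the
#' held-out test portion (or averages scores over K folds), producing the
#' four-way comparison report (OLS, RF, GW-OLS, GW-RF) plus the per-record
#' observed/predicted/residual table for 1:1 plotting. GW bandwidths are not
#' re-selected inside folds unless supplied as `NULL` in `control` (the
#' default control fixes nothing, so GW-OLS selects its bandwidth on each
#' training set).
#'
#' @param frame An [as_area_frame()].
#' @param models Character vector among `"ols", "rf", "gw_ols", "gw_rf"`.
#' @param split A [train_test_split()] result; alternatively give `folds`.
#' @param folds Integer fold vector from [kfold_splits()] for K-fold CV.
#' @param control List of model settings: `rf_params`, `gwols_kernel`,
#'   `gwrf_k`, `gwrf_local_weight`.
#' @param seed Integer seed for model-level randomness.
#' @return An `eval_report`: list with `scores` (tibble: model, rmse, r2,
#'   r2_ss, n_test) and `predictions` (tibble: id, observed, predicted,
#'   residual, model, fold).
#' @export
compare_models <- function(frame, models = c("ols", "rf", "gw_ols", "gw_rf"),
                           split = NULL, folds = NULL, control = list(),
                           seed = 1) {
  if (length(models) == 0) abort_config("At least one model is required.")
  if (is.null(split) && is.null(folds)) {
    abort_config("Provide either a train/test split or a fold vector.")
  }
  roles <- gw_roles(frame)
  fold_sets <- if (!is.null(folds)) {
    purrr::map(sort(unique(folds)), function(f) folds == f)
  } else {
    list(split$test_mask)
  }
  all_scores <- list()
  all_preds <- list()
  for (mi in seq_along(models)) {
    model <- models[mi]
    per_fold <- purrr::imap(fold_sets, function(mask, f) {
      train <- frame[!mask, , drop = FALSE]
      test <- frame[mask, , drop = FALSE]
      pred <- tryCatch(
        fit_and_predict(model, train, test, control, seed),
        error = function(e) {
          gw_abort(paste0("Model '", model, "' failed: ",
                          conditionMessage(e)), "gwareal_error_model")
        })
      obs <- area_outcome(test)
      list(score = score_predictions(obs, pred),
           preds = tibble::tibble(id = area_ids(test), observed = obs,
                                  predicted = pred,
                                  residual = obs - pred,
                                  model = model, fold = f))
    })
    scores <- dplyr::bind_rows(purrr::map(per_fold, "score"))
    all_scores[[mi]] <- tibble::tibble(
      model = model,
      rmse = mean(scores$rmse), r2 = mean(scores$r2),
      r2_ss = mean(scores$r2_ss), n_test = sum(scores$n))
    all_preds[[mi]] <- dplyr::bind_rows(purrr::map(per_fold, "preds"))
  }
  structure(list(scores = dplyr::bind_rows(all_scores),
                 predictions = dplyr::bind_rows(all_preds),
                 models = models, seed = seed,
                 n_folds = length(fold_sets)),
            class = "eval_report")
}

#' @describeIn compare_models The per-model score table.
#' @param x An `eval_report`.
#' @param ... Unused.
#' @export
tidy.eval_report <- function(x, ...) x$scores

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Model comparison over %d test fold(s):\n", x$n_folds))
  print(as.data.frame(x$scores), row.names = FALSE, digits = 4)
  invisible(x)
}
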