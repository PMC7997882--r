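test_that("global forest recovers the driving predictor and handles degeneracy", {
  geom <- make_lattice(17, jitter = 0.2, seed = 1)
  n <- nrow(geom)
  set.seed(2)
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("x", 1:5)))
  d <- dplyr::bind_cols(geom, tibble::as_tibble(X))
  d$y_outcome <- X[, 1]
  af <- as_area_frame(d, outcome = "y_outcome",
                      predictors = paste0("x", 1:5))
  fit <- fit_global_rf(af, rf_params(ntree = 300, seed = 5))
  imp <- fit$importance
  expect_equal(imp$predictor[which.max(imp$incmse_pct)], "x1")
  expect_equal(imp$predictor[which.max(imp$inc_node_purity)], "x1")
  expect_true(all(imp$inc_node_purity >= 0))
  expect_gt(fit$oob_r2, 0.5)

  dc <- d
  dc$y_outcome <- 7
  afc <- as_area_frame(dc, outcome = "y_outcome",
                       predictors = paste0("x", 1:5))
  expect_warning(fitc <- fit_global_rf(afc, rf_params(ntree = 50)),
                 "Constant outcome")
  expect_equal(fitc$oob_mse, 0)
  expect_true(all(fitc$importance$incmse_pct == 0))
})

test_that("forests are deterministic under a fixed seed", {
  af <- toy_frame(6, seed = 3)
  f1 <- fit_global_rf(af, rf_params(ntree = 100, seed = 9))
  f2 <- fit_global_rf(af, rf_params(ntree = 100, seed = 9))
  expect_identical(f1$importance, f2$importance)
  expect_identical(f1$oob_mse, f2$oob_mse)
})

test_that("the early-stopping rule fires after the documented pattern", {
  # two consecutive relative improvements of 0.0005 and 0.0004, both below
  # the 0.001 tolerance, exhaust 2 stopping rounds
  scores <- c(1, 1 * (1 - 5e-4), 1 * (1 - 5e-4) * (1 - 4e-4), 0.5, 0.4)
  expect_equal(gwareal:::early_stop_index(scores, tolerance = 0.001,
                                          rounds = 2), 3)
  # a large improvement resets the counter
  scores2 <- c(1, 0.999, 0.5, 0.499, 0.4988)
  expect_equal(gwareal:::early_stop_index(scores2, tolerance = 0.001,
                                          rounds = 2), 5)
})

test_that("random grid search matches exhaustive scoring on a tiny grid", {
  geom <- make_lattice(10, jitter = 0.2, seed = 7)
  n <- nrow(geom)
  set.seed(8)
  x1 <- rnorm(n); x2 <- rnorm(n)
  d <- dplyr::mutate(geom, x1 = x1, x2 = x2,
                     y_outcome = x1 * x2 + rnorm(n, 0, 0.1))
  af <- as_area_frame(d, outcome = "y_outcome", predictors = c("x1", "x2"))
  grid <- data.frame(ntree = 150, mtry = c(1, 2))
  res <- random_grid_search(af, grid, k_folds = 3, seed = 4)
  expect_equal(res$best$mtry, res$trace$mtry[which.min(res$trace$cv_mse)])
  # the interactive signal needs both predictors per split: mtry = 2 wins
  expect_equal(res$best$mtry, 2)
  expect_equal(nrow(res$trace), 2)

  res1 <- random_grid_search(af, grid[1, , drop = FALSE], k_folds = 3,
                             seed = 4)
  expect_equal(nrow(res1$trace), 1)
  expect_warning(random_grid_search(af, grid, k_folds = 3, n_draws = 5,
                                    seed = 4), "capped")
  expect_error(random_grid_search(af, grid[0, ], k_folds = 3),
               class = "gwareal_error_config")
})

test_that("partial dependence reflects signal, flatness and independence", {
  geom <- make_lattice(15, jitter = 0.2, seed = 2)
  n <- nrow(geom)
  set.seed(3)
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("x", 1:3)))
  d <- dplyr::bind_cols(geom, tibble::as_tibble(X))
  d$y_outcome <- 3 * X[, 1] + rnorm(n, 0, 0.3)
  af <- as_area_frame(d, outcome = "y_outcome",
                      predictors = paste0("x", 1:3))
  fit <- fit_global_rf(af, rf_params(ntree = 200, seed = 6))
  pd <- partial_dependence(fit, "x1", grid_points = 15)
  expect_true(all(diff(pd$pdp) >= -1e-8))

  # averaging the PDP over the feature's own distribution recovers the mean
  # prediction when the design is independent
  pd_at_obs <- partial_dependence(fit, "x2", grid = X[, 2])
  expect_lt(abs(mean(pd_at_obs$pdp) - mean(predict(fit$forest, X))), 0.05)

  expect_error(partial_dependence(fit, "nope"),
               class = "gwareal_error_config")

  dc <- d
  dc$y_outcome <- 1
  afc <- as_area_frame(dc, outcome = "y_outcome",
                       predictors = paste0("x", 1:3))
  fitc <- suppressWarnings(fit_global_rf(afc, rf_params(ntree = 50)))
  pdc <- partial_dependence(fitc, "x1", grid_points = 5)
  expect_true(all(pdc$pdp == 1))
})

test_that("GW-RF at k = n with a shared seed equals the global forest", {
  af <- toy_frame(6, seed = 11)
  n <- nrow(af)
  fit <- fit_gwrf(af, k_neighbors = n, params = rf_params(ntree = 80),
                  seed = 5, force_global_seed = TRUE, keep_forests = FALSE)
  expect_equal(fit$local$oob_mse, rep(fit$global$oob_mse, n),
               tolerance = 1e-12)
})

test_that("GW-RF output is deterministic, ranked and well-formed", {
  af <- toy_frame(7, seed = 13)
  f1 <- fit_gwrf(af, k_neighbors = 15, params = rf_params(ntree = 60),
                 seed = 21, keep_forests = FALSE)
  f2 <- fit_gwrf(af, k_neighbors = 15, params = rf_params(ntree = 60),
                 seed = 21, keep_forests = FALSE)
  expect_identical(f1$incmse, f2$incmse)
  expect_true(all(f1$nodepurity >= 0))
  expect_true(all(f1$local$pseudo_r2 <= 1, na.rm = TRUE))
  # each location's ranks are a permutation of 1..p
  expect_true(all(apply(f1$ranks, 1, function(r) all(sort(r) == 1:2))))

  expect_error(fit_gwrf(af, k_neighbors = 5), class = "gwareal_error_config")
})

test_that("importance ranking aggregates shares and breaks ties by column order", {
  expect_equal(gwareal:::rank_importance(c(5, 1)), c(1, 2))
  expect_equal(gwareal:::rank_importance(c(3, 3, 1)), c(1, 2, 3))

  af <- toy_frame(6, seed = 17)
  fit <- fit_gwrf(af, k_neighbors = 12, params = rf_params(ntree = 60),
                  seed = 3, keep_forests = FALSE)
  rs <- local_importance_ranking(fit)
  expect_equal(sum(rs$pct_rank1), 100, tolerance = 1e-9)
  expect_equal(sum(rs$pct_rank2), 100, tolerance = 1e-9)
  expect_equal(attr(rs, "n_excluded"), 0)

  tab2 <- gwrf_summary(fit)
  expect_true(all(c("oob_mse", "pseudo_r2") %in% tab2$quantity))
  expect_true(all(tab2$min <= tab2$max))
})

test_that("GW-RF predictions blend local and global forests", {
  af <- toy_frame(6, seed = 19)
  fit <- fit_gwrf(af, k_neighbors = 12, params = rf_params(ntree = 60),
                  seed = 7, keep_forests = TRUE)
  newdata <- tibble::as_tibble(af)[c(2, 20), ]
  p_global <- predict(fit, newdata, local_weight = 0)
  roles_pred <- as.matrix(newdata[, predictor_names(af)])
  expect_equal(p_global, as.numeric(predict(fit$global$forest, roles_pred)),
               tolerance = 1e-12)
  p_local <- predict(fit, newdata, local_weight = 1)
  expect_equal(p_local[1],
               as.numeric(predict(fit$forests[[2]],
                                  roles_pred[1, , drop = FALSE])),
               tolerance = 1e-12)
  p_half <- predict(fit, newdata, local_weight = 0.5)
  expect_equal(p_half, 0.5 * p_local + 0.5 * p_global, tolerance = 1e-12)

  expect_error(predict(fit, newdata[, -3], local_weight = 1),
               class = "gwareal_error_schema")
  expect_error(predict(fit, newdata, local_weight = 2),
               class = "gwareal_error_config")
})
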