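test_that("local WLS solves exact, zero-weight and random-weight designs", {
  X <- cbind(1, 0:3)
  y <- c(1, 3, 5, 7)
  fit <- fit_local_wls(X, y, rep(1, 4))
  expect_equal(unname(fit$beta), c(1, 2), tolerance = 1e-12)

  w <- c(1, 1, 1, 0)
  fit0 <- fit_local_wls(X, y, w)
  ols3 <- lm(y[1:3] ~ X[1:3, 2])
  expect_equal(unname(fit0$beta), unname(coef(ols3)), tolerance = 1e-10)

  set.seed(17)
  for (rep in 1:50) {
    n <- sample(8:15, 1)
    p <- sample(1:3, 1)
    Xr <- cbind(1, matrix(rnorm(n * p), n, p))
    yr <- rnorm(n)
    wr <- runif(n, 0.1, 2)
    expect_equal(unname(fit_local_wls(Xr, yr, wr)$beta),
                 oracle_wls(Xr, yr, wr), tolerance = 1e-10)
  }

  expect_error(fit_local_wls(cbind(1, c(1, 1, 1)), 1:3, c(1, 1, 1)),
               class = "gwareal_error_singular")
})

test_that("hat rows reproduce fitted values", {
  set.seed(23)
  X <- cbind(1, matrix(rnorm(16), 8, 2))
  y <- rnorm(8)
  w <- runif(8, 0.2, 1)
  w[3] <- 1
  fit <- fit_local_wls(X, y, w, focal = 3)
  expect_equal(sum(fit$hat_row * y), sum(X[3, ] * fit$beta),
               tolerance = 1e-10)
})

test_that("AICc matches a from-scratch hat-matrix recomputation", {
  sc <- synth_scenario("gradient", n_side = 10, seed = 21)
  frame <- sc$frame
  X <- cbind(1, area_predictors(frame))
  y <- area_outcome(frame)
  coords <- area_coords(frame)
  n <- nrow(X)
  D <- pairwise_distances(coords)
  for (k in c(30, 60, n)) {
    kern <- kernel_spec("bisquare", adaptive = TRUE, bandwidth = k)
    bw <- adaptive_bandwidth(coords, min(k, n - 1))
    S <- matrix(0, n, n)
    yhat <- numeric(n)
    for (i in seq_len(n)) {
      w <- kernel_weights(D[i, ], bw[i], "bisquare")
      w[i] <- 1
      lf <- fit_local_wls(X, y, w, focal = i)
      S[i, ] <- lf$hat_row
      yhat[i] <- sum(X[i, ] * lf$beta)
    }
    rss <- sum((y - yhat)^2)
    tr_s <- sum(diag(S))
    sigma <- sqrt(rss / n)
    aicc_oracle <- 2 * n * log(sigma) + n * log(2 * pi) +
      n * (n + tr_s) / (n - 2 - tr_s)
    expect_equal(gwols_aicc(frame, kern), aicc_oracle, tolerance = 1e-8)
  }
})

test_that("AICc prefers local fits under heterogeneous truth", {
  sc <- synth_scenario("gradient", n_side = 10, seed = 8)
  n <- nrow(sc$frame)
  aicc_local <- gwols_aicc(sc$frame,
                           kernel_spec("bisquare", TRUE, bandwidth = 40))
  aicc_global <- gwols_aicc(sc$frame,
                            kernel_spec("bisquare", TRUE, bandwidth = n))
  expect_lt(aicc_local, aicc_global)
})

test_that("bandwidth selection honors grids and homogeneous truth", {
  sc <- synth_scenario("gradient", n_side = 10, seed = 4)
  expect_equal(select_bandwidth(sc$frame, candidates = 42)$bandwidth, 42L)

  grid <- c(20, 40, 80, 100)
  sel <- select_bandwidth(sc$frame, candidates = grid)
  aiccs <- vapply(grid, function(k) {
    gwols_aicc(sc$frame, kernel_spec("bisquare", TRUE, bandwidth = k))
  }, numeric(1))
  expect_equal(sel$bandwidth, grid[which.min(aiccs)])
  expect_equal(sel$aicc, min(aiccs), tolerance = 1e-10)

  # when the truth is spatially constant, the largest candidate should win
  # in the clear majority of replicates
  hits <- vapply(1:10, function(s) {
    sch <- synth_scenario("homogeneous", n_side = 8, seed = s)
    select_bandwidth(sch$frame, candidates = c(20, 40, 64))$bandwidth == 64L
  }, logical(1))
  expect_gte(sum(hits), 8)

  expect_error(select_bandwidth(sc$frame, candidates = integer(0)),
               class = "gwareal_error_config")
})

test_that("full-bandwidth boxcar GW-OLS collapses to the global model", {
  sc <- synth_scenario("homogeneous", n_side = 8, seed = 6)
  n <- nrow(sc$frame)
  fit <- fit_gwols(sc$frame, kernel_spec("boxcar", TRUE, bandwidth = n))
  ols <- lm(y_outcome ~ x1 + x2, data = sc$frame)
  sm <- summary(ols)
  for (i in c(1, 17, n)) {
    expect_equal(unname(fit$beta[i, ]), unname(coef(ols)), tolerance = 1e-8)
  }
  expect_equal(unname(fit$se[1, ]), unname(sm$coefficients[, 2]),
               tolerance = 1e-8)
  g <- glance(fit)
  expect_equal(g$r.squared, sm$r.squared, tolerance = 1e-8)
  expect_equal(g$adj.r.squared, sm$adj.r.squared, tolerance = 1e-8)
  expect_equal(g$enp, 3, tolerance = 1e-8)
})

test_that("ENP decreases as the adaptive bandwidth grows", {
  sc <- synth_scenario("gradient", n_side = 8, seed = 9)
  enps <- vapply(c(15, 25, 40, 64), function(k) {
    fit <- fit_gwols(sc$frame, kernel_spec("bisquare", TRUE, bandwidth = k))
    fit$global$enp
  }, numeric(1))
  expect_true(all(diff(enps) < 0))
})

test_that("adjusted p-values apply the dependent-test correction", {
  expect_equal(adjusted_p_values(0, enp = 10, p_model = 5, n = 100), 1)
  t <- c(-2.2, 0.4, 3.1)
  expect_equal(adjusted_p_values(t, enp = 3, p_model = 3, n = 50),
               2 * pt(-abs(t), df = 47), tolerance = 1e-12)
  p_raw <- 2 * pt(-abs(t), df = 100 - 12)
  expect_equal(adjusted_p_values(t, enp = 12, p_model = 3, n = 100),
               pmin(1, p_raw * 4), tolerance = 1e-12)
  expect_error(adjusted_p_values(t, enp = 2, p_model = 3, n = 100),
               class = "gwareal_error_config")
})

test_that("p-value columns are proper and ordered", {
  sc <- synth_scenario("gradient", n_side = 8, seed = 10)
  fit <- fit_gwols(sc$frame, kernel_spec("bisquare", TRUE, bandwidth = 30))
  td <- tidy(fit)
  expect_true(all(td$p.value > 0 & td$p.value <= 1))
  expect_true(all(td$p.adjusted >= td$p.value - 1e-15))
  expect_true(all(td$p.adjusted <= 1))
  expect_equal(unique(td$id), area_ids(sc$frame))
})

test_that("local VIFs match closed forms and flag duplicates", {
  geom <- make_lattice(7, jitter = 0, seed = 2)
  n <- nrow(geom)
  set.seed(41)
  z1 <- rnorm(n)
  z2 <- rnorm(n)
  # exactly orthogonal pair
  z2o <- residuals(lm(z2 ~ z1))
  d <- dplyr::mutate(geom, x1 = z1 - mean(z1), x2 = z2o,
                     y_outcome = rnorm(n))
  af <- as_area_frame(d, outcome = "y_outcome", predictors = c("x1", "x2"))
  v <- local_vif(af, kernel_spec("boxcar", TRUE, bandwidth = n))
  expect_true(all(abs(v$vif_x1 - 1) < 1e-6))
  expect_true(all(abs(v$vif_x2 - 1) < 1e-6))

  ddup <- dplyr::mutate(d, x2 = x1)
  afd <- as_area_frame(ddup, outcome = "y_outcome",
                       predictors = c("x1", "x2"))
  vd <- local_vif(afd, kernel_spec("boxcar", TRUE, bandwidth = n))
  expect_true(all(is.infinite(vd$vif_x1)))
  expect_true(all(is.infinite(vd$vif_x2)))

  af1 <- as_area_frame(d, outcome = "y_outcome", predictors = "x1")
  expect_error(local_vif(af1, kernel_spec("boxcar", TRUE, bandwidth = n)),
               class = "gwareal_error_config")
})

test_that("GW-OLS predictions hit exact and comparative benchmarks", {
  sc <- synth_scenario("homogeneous", n_side = 8, noise_sd = 0, seed = 12)
  n <- nrow(sc$frame)
  fit <- fit_gwols(sc$frame, kernel_spec("boxcar", TRUE, bandwidth = n))
  newdata <- tibble::as_tibble(sc$frame)[3, ]
  ols <- lm(y_outcome ~ x1 + x2, data = sc$frame)
  expect_equal(predict(fit, newdata),
               unname(predict(ols, newdata)), tolerance = 1e-8)
  expect_equal(predict(fit, newdata), unname(newdata$y_outcome), tolerance = 1e-8)

  # heterogeneous truth: local calibration beats the global line out of sample
  scg <- synth_scenario("gradient", n_side = 20, seed = 31)
  sp <- train_test_split(scg$frame, 80, seed = 3)
  fitg <- fit_gwols(sp$train, kernel_spec("bisquare", TRUE, bandwidth = 60))
  pred_gw <- predict(fitg, sp$test)
  olsg <- lm(y_outcome ~ x1 + x2, data = sp$train)
  pred_ols <- predict(olsg, newdata = sp$test)
  obs <- area_outcome(sp$test)
  expect_lt(sqrt(mean((obs - pred_gw)^2)), sqrt(mean((obs - pred_ols)^2)))
})

test_that("coefficient quartile summaries span the local surfaces", {
  sc <- synth_scenario("gradient", n_side = 8, seed = 14)
  fit <- fit_gwols(sc$frame, kernel_spec("bisquare", TRUE, bandwidth = 30))
  cq <- coef_quartiles(fit)
  expect_equal(cq$term, fit$coef_names)
  expect_true(all(cq$min <= cq$q1 & cq$q1 <= cq$median &
                    cq$median <= cq$q3 & cq$q3 <= cq$max))
  expect_equal(cq$min[2], min(fit$beta[, 2]))
})
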