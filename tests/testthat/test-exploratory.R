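make_field_frame <- function(geom, f) {
  d <- dplyr::mutate(geom, f = f, y_outcome = f, x1 = 1)
  as_area_frame(d, outcome = "y_outcome", predictors = "x1")
}

test_that("Gi* matches explicit per-location summation and flags hotspots", {
  geom <- make_lattice(5, jitter = 0)
  f <- rep(0, 25)
  block <- which(geom$x %in% c(1, 2) & geom$y %in% c(1, 2))
  f[block] <- 1
  af <- make_field_frame(geom, f)
  W <- build_weight_matrix(af, "knn_binary", k = 8, include_self = TRUE)
  res <- getis_ord_gi_star(af, "f", W = W)

  oracle <- vapply(1:25, function(i) oracle_gi_z(f, W$w, i), numeric(1))
  expect_equal(res$z, oracle, tolerance = 1e-10)
  # the maximum z is attained at a block cell (ties with adjacent cells
  # whose neighborhood covers the whole block are allowed)
  expect_equal(max(res$z[block]), max(res$z), tolerance = 1e-12)
  expect_true(all(res$p > 0 & res$p <= 1))
  expect_equal(res$id, area_ids(af))

  expect_error(getis_ord_gi_star(make_field_frame(geom, rep(3, 25)), "f"),
               class = "gwareal_error_degenerate")
})

test_that("hotspot classes follow the 90/95/99 z thresholds", {
  z <- c(2.0, -2.6, 1.7, -1.7, 2.6, 0.5, -1.0)
  expect_equal(gwareal:::classify_z(z),
               c("hot95", "cold99", "hot90", "cold90", "hot99", "ns", "ns"))
})

test_that("bivariate LMI reduces to univariate local Moran when y = x", {
  geom <- make_lattice(6, jitter = 0.2, seed = 3)
  set.seed(9)
  f <- rnorm(36)
  af <- make_field_frame(geom, f)
  W <- build_weight_matrix(af, "knn_binary", k = 8, row_standardize = TRUE)
  res <- bivariate_local_moran(af, "f", "f", W = W, n_perm = 99, seed = 1)
  # classic univariate local Moran, scaled to the population-standardized
  # convention (factor n * m2 / sum((x - xbar)^2) = 1)
  expect_equal(res$local_i, oracle_local_moran(f, W$w), tolerance = 1e-10)
})

test_that("checkerboard fields give local and global I of -1 under rook weights", {
  geom <- make_lattice(4, jitter = 0)
  f <- (-1)^(geom$x + geom$y)
  af <- make_field_frame(geom, f)
  W <- rook_weights(af)
  res <- bivariate_local_moran(af, "f", "f", W = W, n_perm = 99, seed = 1)
  expect_equal(res$local_i, rep(-1, 16), tolerance = 1e-12)
  expect_equal(global_bivariate_moran(af, "f", "f", W = W), -1,
               tolerance = 1e-12)

  # 2x2 checkerboard: every lag is the opposite value
  g2 <- make_lattice(2, jitter = 0)
  f2 <- c(1, -1, -1, 1)
  af2 <- make_field_frame(g2, f2)
  W2 <- build_weight_matrix(af2, "knn_binary", k = 2, row_standardize = TRUE)
  res2 <- bivariate_local_moran(af2, "f", "f", W = W2, n_perm = 99, seed = 1)
  expect_equal(res2$local_i, rep(-1, 4), tolerance = 1e-12)
})

test_that("LMI permutation inference is seeded, bounded and stable", {
  geom <- make_lattice(7, jitter = 0.2, seed = 5)
  set.seed(21)
  d <- dplyr::mutate(geom, y_outcome = rnorm(49), x1 = rnorm(49))
  af <- as_area_frame(d, outcome = "y_outcome", predictors = "x1")
  W <- build_weight_matrix(af, "knn_binary", k = 8, row_standardize = TRUE)
  r1 <- bivariate_local_moran(af, "y_outcome", "x1", W = W, n_perm = 199,
                              seed = 7)
  r2 <- bivariate_local_moran(af, "y_outcome", "x1", W = W, n_perm = 199,
                              seed = 7)
  expect_identical(r1, r2)
  expect_true(all(r1$p_perm >= 1 / 200 & r1$p_perm <= 1))
  expect_true(all(r1$cluster[r1$p_perm >= 0.05] == "ns"))

  # richer permutation budget changes few classes on this fixed example
  r3 <- bivariate_local_moran(af, "y_outcome", "x1", W = W, n_perm = 999,
                              seed = 7)
  expect_lt(mean(r1$cluster != r3$cluster), 0.1)

  expect_error(
    bivariate_local_moran(make_field_frame(geom, rep(1, 49)), "f", "f"),
    class = "gwareal_error_degenerate")
  expect_error(
    bivariate_local_moran(af, "y_outcome", "x1", n_perm = 50),
    class = "gwareal_error_config")
})

test_that("GW correlation hits its global and exact limits", {
  geom <- make_lattice(6, jitter = 0.2, seed = 2)
  set.seed(31)
  d <- dplyr::mutate(geom, y_outcome = rnorm(36), x1 = rnorm(36))
  af <- as_area_frame(d, outcome = "y_outcome", predictors = "x1")

  res <- gw_correlation(af, "x1", "y_outcome",
                        kernel_spec("boxcar", adaptive = TRUE, bandwidth = 36))
  expect_equal(res$r, rep(cor(d$x1, d$y_outcome), 36), tolerance = 1e-10)

  d2 <- dplyr::mutate(d, y_outcome = 2 * x1 + 3)
  af2 <- as_area_frame(d2, outcome = "y_outcome", predictors = "x1")
  res2 <- gw_correlation(af2, "x1", "y_outcome",
                         kernel_spec("bisquare", adaptive = TRUE,
                                     bandwidth = 10))
  expect_equal(res2$r, rep(1, 36), tolerance = 1e-10)
})

test_that("GW correlation localizes a two-regime association", {
  geom <- make_lattice(20, jitter = 0.2, seed = 13)
  set.seed(13)
  x_field <- rnorm(400)
  west <- geom$x < mean(range(geom$x))
  y_field <- ifelse(west, x_field, -x_field) + rnorm(400, 0, 0.2)
  d <- dplyr::mutate(geom, x1 = x_field, y_outcome = y_field)
  af <- as_area_frame(d, outcome = "y_outcome", predictors = "x1")
  res <- gw_correlation(af, "x1", "y_outcome",
                        kernel_spec("bisquare", adaptive = TRUE,
                                    bandwidth = 30))
  interior <- abs(geom$x - mean(range(geom$x))) > 2
  agree <- sign(res$r[interior]) == ifelse(west[interior], 1, -1)
  expect_gte(mean(agree), 0.95)
})
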