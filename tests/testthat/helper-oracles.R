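# Independent brute-force oracles used across tests. These intentionally use
# naive explicit summation, not the package's vectorized paths.

# Weighted least squares by explicit normal-equation sums.
oracle_wls <- function(X, y, w) {
  p <- ncol(X)
  A <- matrix(0, p, p)
  b <- numeric(p)
  for (i in seq_len(nrow(X))) {
    for (k in seq_len(p)) {
      b[k] <- b[k] + w[i] * X[i, k] * y[i]
      for (l in seq_len(p)) {
        A[k, l] <- A[k, l] + w[i] * X[i, k] * X[i, l]
      }
    }
  }
  solve(A, b)
}

# Getis-Ord Gi* z-score at one location by explicit summation.
oracle_gi_z <- function(x, wm, i) {
  n <- length(x)
  xbar <- mean(x)
  s <- sqrt(sum(x^2) / n - xbar^2)
  sw <- sum(wm[i, ])
  sw2 <- sum(wm[i, ]^2)
  num <- sum(wm[i, ] * x) - xbar * sw
  num / (s * sqrt((n * sw2 - sw^2) / (n - 1)))
}

# Univariate local Moran's I via the classic (non-standardized-variable) form.
oracle_local_moran <- function(x, wm) {
  n <- length(x)
  xc <- x - mean(x)
  m2 <- sum(xc^2) / n
  vapply(seq_len(n), function(i) {
    (xc[i] / m2) * sum(wm[i, ] * xc)
  }, numeric(1))
}

# Rook contiguity on a lattice built as a boxcar band at distance 1.
rook_weights <- function(frame, row_standardize = TRUE) {
  build_weight_matrix(frame, "kernel",
                      kernel = kernel_spec("boxcar", adaptive = FALSE,
                                           bandwidth = 1),
                      row_standardize = row_standardize)
}

# Small areal frame on a jittered lattice with i.i.d. fields.
toy_frame <- function(n_side = 5, seed = 1, p = 2, jitter = 0) {
  geom <- make_lattice(n_side, jitter = jitter, seed = seed)
  set.seed(seed + 1000)
  d <- dplyr::bind_cols(
    geom,
    tibble::as_tibble(matrix(rnorm(nrow(geom) * p), ncol = p,
                             dimnames = list(NULL, paste0("x", 1:p)))))
  d$y_outcome <- rnorm(nrow(d))
  as_area_frame(d, outcome = "y_outcome", predictors = paste0("x", 1:p))
}
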