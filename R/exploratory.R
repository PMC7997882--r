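#' Getis-Ord Gi* hotspot statistic
#'
#' Identifies clusters of high values (hot spots) and low values (cold spots)
#' of a field over areal units. For each location i with self-inclusive
#' weights \eqn{w_{ij}}:
#' \deqn{z_i = \frac{\sum_j w_{ij} x_j - \bar X \sum_j w_{ij}}
#'   {S \sqrt{\left[n \sum_j w_{ij}^2 - (\sum_j w_{ij})^2\right] / (n-1)}}}
#' with \eqn{\bar X} and \eqn{S} the global mean and (population) standard
#' deviation over all n units. Two-sided p-values come from the standard
#' normal approximation (the convention of the desktop GIS tools that
#' popularized the statistic); classes follow the usual 90/95/99% z
#' thresholds (1.645, 1.96, 2.576).
#'
#' @param frame An [as_area_frame()].
#' @param field Column name of the field to analyze (default: the outcome).
#' @param W Optional self-inclusive [build_weight_matrix()]; by default a
#'   binary k-NN (k = 8) neighborhood plus self is built.
#' @param k Neighbor count used when `W` is not supplied.
#' @return A tibble with columns `id`, `gi_star`, `z`, `p`, `class`
#'   (`hot99, hot95, hot90, ns, cold90, cold95, cold99`), in input order.
#' @export
getis_ord_gi_star <- function(frame, field = NULL, W = NULL, k = 8) {
  field <- field %||% outcome_name(frame)
  x <- frame[[field]]
  if (is.null(x)) abort_schema(paste0("Unknown field: ", field))
  n <- length(x)
  if (sd(x) == 0) {
    abort_degenerate("Field has zero variance; Gi* is undefined (S = 0).")
  }
  if (is.null(W)) {
    W <- build_weight_matrix(frame, "knn_binary", k = k, include_self = TRUE)
  }
  if (!W$include_self) {
    abort_config("Gi* requires self-inclusive weights (include_self = TRUE).")
  }
  wm <- W$w
  xbar <- mean(x)
  s_pop <- sqrt(mean(x^2) - xbar^2)
  sw <- rowSums(wm)
  sw2 <- rowSums(wm^2)
  num <- as.numeric(wm %*% x) - xbar * sw
  den <- s_pop * sqrt((n * sw2 - sw^2) / (n - 1))
  z <- num / den
  p <- 2 * pnorm(-abs(z))
  tibble::tibble(
    id = area_ids(frame),
    gi_star = as.numeric(wm %*% x) / sum(x),
    z = z,
    p = p,
    class = classify_z(z)
  )
}

classify_z <- function(z) {
  dplyr::case_when(
    z >= 2.576 ~ "hot99",
    z >= 1.96 ~ "hot95",
    z >= 1.645 ~ "hot90",
    z <= -2.576 ~ "cold99",
    z <= -1.96 ~ "cold95",
    z <= -1.645 ~ "cold90",
    TRUE ~ "ns"
  )
}

# Population z-standardization (divide by sqrt(mean squared deviation)), the
# convention under which a checkerboard field standardizes to exactly +/-1.
standardize_pop <- function(x) {
  s <- sqrt(mean((x - mean(x))^2))
  if (s == 0) abort_degenerate("Field has zero variance.")
  (x - mean(x)) / s
}

#' Bivariate local Moran's I with conditional permutation inference
#'
#' Measures, at each location, the association between one variable there and
#' the average of another variable in its neighborhood (the spatial lag):
#' \eqn{I_i = \tilde x_i \sum_j w_{ij} \tilde y_j} with population
#' z-standardized \eqn{\tilde x, \tilde y} and row-standardized weights.
#' Inference is by conditional permutation: \eqn{\tilde x_i} is held fixed
#' while \eqn{\tilde y} is permuted over the other n - 1 locations;
#' the two-sided pseudo p-value is
#' `(count(|I_perm| >= |I_i|) + 1) / (n_perm + 1)`. Locations are classified
#' High-High / Low-Low / High-Low / Low-High by the signs of \eqn{\tilde x_i}
#' and the lag, but only where pseudo-p < `alpha`; otherwise `ns`.
#' With `y = x` the statistic reduces to the univariate local Moran's I.
#'
#' @param frame An [as_area_frame()].
#' @param x_name,y_name Column names of the focal and lagged variables.
#' @param W Optional row-standardized [build_weight_matrix()]; default
#'   binary k-NN (k = 8) row-standardized.
#' @param n_perm Number of conditional permutations (>= 99; default 999).
#' @param alpha Significance level for cluster assignment (default 0.05).
#' @param seed Integer seed for the permutations.
#' @param k Neighbor count used when `W` is not supplied.
#' @return A tibble with `id`, `local_i`, `lag`, `p_perm`, `cluster`
#'   (`HH, LL, HL, LH, ns`), in input order.
#' @export
bivariate_local_moran <- function(frame, x_name, y_name, W = NULL,
                                  n_perm = 999, alpha = 0.05, seed = 1,
                                  k = 8) {
  if (n_perm < 99) abort_config("n_perm must be >= 99.")
  x <- frame[[x_name]]
  y <- frame[[y_name]]
  if (is.null(x) || is.null(y)) abort_schema("Unknown x_name or y_name.")
  xt <- standardize_pop(x)
  yt <- standardize_pop(y)
  if (is.null(W)) {
    W <- build_weight_matrix(frame, "knn_binary", k = k,
                             row_standardize = TRUE)
  }
  wm <- W$w
  n <- length(xt)
  lag <- as.numeric(wm %*% yt)
  local_i <- xt * lag
  set.seed(seed)
  p_perm <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(wm[i, ] != 0)
    nb <- nb[nb != i]
    w_nb <- wm[i, nb]
    pool <- yt[-i]
    m <- length(nb)
    # n_perm independent draws of m values without replacement from the pool
    samp <- matrix(0, n_perm, m)
    for (r in seq_len(n_perm)) {
      samp[r, ] <- pool[sample.int(length(pool), m)]
    }
    i_perm <- xt[i] * as.numeric(samp %*% w_nb)
    p_perm[i] <- (sum(abs(i_perm) >= abs(local_i[i])) + 1) / (n_perm + 1)
  }
  cluster <- dplyr::case_when(
    p_perm >= alpha ~ "ns",
    xt > 0 & lag > 0 ~ "HH",
    xt < 0 & lag < 0 ~ "LL",
    xt > 0 & lag < 0 ~ "HL",
    TRUE ~ "LH"
  )
  tibble::tibble(id = area_ids(frame), local_i = local_i, lag = lag,
                 p_perm = p_perm, cluster = cluster)
}

#' Global bivariate Moran's I
#'
#' \eqn{I = \frac{1}{n} \sum_i \tilde x_i \sum_j w_{ij} \tilde y_j} with
#' population-standardized variables and row-standardized weights — the mean
#' over locations of the bivariate local Moran's I.
#'
#' @inheritParams bivariate_local_moran
#' @return A single numeric value.
#' @export
global_bivariate_moran <- function(frame, x_name, y_name, W = NULL, k = 8) {
  x <- frame[[x_name]]
  y <- frame[[y_name]]
  if (is.null(x) || is.null(y)) abort_schema("Unknown x_name or y_name.")
  xt <- standardize_pop(x)
  yt <- standardize_pop(y)
  if (is.null(W)) {
    W <- build_weight_matrix(frame, "knn_binary", k = k,
                             row_standardize = TRUE)
  }
  mean(xt * as.numeric(W$w %*% yt))
}

#' Geographically weighted Pearson correlation
#'
#' Computes, at every location, the kernel-weighted Pearson correlation
#' between two fields — a preliminary, model-free look at non-stationarity in
#' a bivariate relationship. With kernel weights normalized to sum to one,
#' \eqn{r_i = \mathrm{cov}_w(x, y) / \sqrt{\mathrm{var}_w(x)\,
#' \mathrm{var}_w(y)}}. Locations where either local weighted variance is
#' zero are flagged undefined (`r = NA`).
#'
#' @param frame An [as_area_frame()].
#' @param x_name,y_name Column names of the two fields.
#' @param kernel A [kernel_spec()]; the default is the adaptive bi-square
#'   kernel conventional for GW summary statistics.
#' @return A tibble with `id`, `r`, `undefined`, in input order.
#' @export
gw_correlation <- function(frame, x_name, y_name,
                           kernel = kernel_spec("bisquare", adaptive = TRUE,
                                                bandwidth = 30)) {
  x <- frame[[x_name]]
  y <- frame[[y_name]]
  if (is.null(x) || is.null(y)) abort_schema("Unknown x_name or y_name.")
  if (is.null(kernel$bandwidth)) {
    abort_config("gw_correlation requires an explicit kernel bandwidth.")
  }
  coords <- area_coords(frame)
  D <- pairwise_distances(coords)
  bw <- kernel_bandwidths(coords, kernel)
  n <- nrow(coords)
  r <- numeric(n)
  undefined <- logical(n)
  for (i in seq_len(n)) {
    w <- kernel_row_weights(D, i, kernel, bw)
    w <- w / sum(w)
    mx <- sum(w * x); my <- sum(w * y)
    vx <- sum(w * (x - mx)^2); vy <- sum(w * (y - my)^2)
    if (vx <= 0 || vy <= 0) {
      r[i] <- NA_real_
      undefined[i] <- TRUE
    } else {
      r[i] <- sum(w * (x - mx) * (y - my)) / sqrt(vx * vy)
    }
  }
  if (all(undefined)) {
    abort_degenerate("Local correlation undefined at every location.")
  }
  tibble::tibble(id = area_ids(frame), r = r, undefined = undefined)
}
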