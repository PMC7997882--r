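#' Jittered lattice geometry for synthetic areal data
#'
#' Places `n_side^2` areal-unit centroids on a unit-spaced square grid, each
#' displaced independently and uniformly by up to `jitter` of the cell size per
#' axis. Ids run `0 .. n-1` row-major (x fastest). Coordinates are abstract
#' planar units: the downstream analyses only use relative distances, so no
#' coordinate reference system is attached.
#'
#' @param n_side Lattice side length (>= 2); n = n_side^2 units.
#' @param jitter Displacement fraction in `[0, 0.5)`.
#' @param seed Integer seed; identical arguments give bit-identical output.
#' @return A tibble with columns `id`, `x`, `y`.
#' @export
#' @examples
#' make_lattice(3)
make_lattice <- function(n_side, jitter = 0, seed = 1) {
  if (!is.numeric(n_side) || n_side < 2) {
    abort_config("n_side must be an integer >= 2.")
  }
  if (jitter < 0 || jitter >= 0.5) {
    abort_config("jitter must lie in [0, 0.5).")
  }
  n_side <- as.integer(n_side)
  n <- n_side^2
  gx <- rep(seq_len(n_side) - 1, times = n_side)
  gy <- rep(seq_len(n_side) - 1, each = n_side)
  set.seed(seed)
  dx <- runif(n, -jitter, jitter)
  dy <- runif(n, -jitter, jitter)
  tibble::tibble(id = 0:(n - 1), x = gx + dx, y = gy + dy)
}

#' Simulate a spatially varying coefficient surface
#'
#' Produces one local coefficient value per areal unit — the synthetic analog
#' of a geographically weighted regression's location-specific coefficients.
#' Three deterministic families are supported:
#' \describe{
#'   \item{constant}{`params$value` everywhere.}
#'   \item{gradient}{affine in the coordinates, running from `params$from` at
#'     the low end to `params$to` at the high end of `params$axis`
#'     (`"x"` or `"y"`), normalized by the observed coordinate range.}
#'   \item{gaussian_bump}{`params$base + params$height *
#'     exp(-d^2 / (2 * params$width^2))` with `d` the distance to
#'     `params$center` (length-2).}
#' }
#'
#' @param geometry A data frame with `x`, `y` columns (e.g. [make_lattice()]).
#' @param kind One of `"constant"`, `"gradient"`, `"gaussian_bump"`.
#' @param params Named list of parameters for the chosen kind (see Details).
#' @return A numeric vector of length `nrow(geometry)` with attributes
#'   `kind` and `params`.
#' @export
simulate_coefficient_surface <- function(geometry, kind, params = list()) {
  x <- geometry$x
  y <- geometry$y
  values <- switch(
    kind,
    constant = rep(params$value %||% 0, length(x)),
    gradient = {
      axis <- params$axis %||% "x"
      from <- params$from %||% 0
      to <- params$to %||% 1
      u <- if (axis == "x") x else y
      rng <- range(u)
      t <- if (diff(rng) == 0) rep(0, length(u)) else (u - rng[1]) / diff(rng)
      from + (to - from) * t
    },
    gaussian_bump = {
      center <- params$center %||% c(mean(range(x)), mean(range(y)))
      width <- params$width %||% 1
      d2 <- (x - center[1])^2 + (y - center[2])^2
      (params$base %||% 0) + (params$height %||% 1) * exp(-d2 / (2 * width^2))
    },
    abort_config(paste0("Unknown surface kind: '", kind, "'."))
  )
  structure(values, kind = kind, params = params)
}

#' Simulate spatially autocorrelated predictors
#'
#' Builds `p` unit-variance predictor fields, each a mixture of a smooth
#' regional component — Gaussian-kernel-smoothed white noise with
#' length-scale `spatial_range` (in coordinate units) — and an unsmoothed
#' unit-to-unit component weighted by `nugget`. The nugget mirrors the short-
#' range variability areal socioeconomic surfaces always carry on top of
#' their regional trends; without it local regressions would face designs
#' with no local predictor variation. `spatial_range = 0` gives i.i.d.
#' fields. Pairwise cross-correlation is induced by mixing each field with a
#' shared latent field: with mixing weight `sqrt(predictor_corr)` the
#' expected pairwise correlation equals `predictor_corr`. Columns are exactly
#' standardized (mean 0, sample variance 1) after generation.
#'
#' @inheritParams simulate_coefficient_surface
#' @param p Number of predictors (>= 1).
#' @param spatial_range Smoothing length-scale in coordinate units (>= 0).
#' @param predictor_corr Target pairwise correlation in `[0, 1)`.
#' @param nugget Fraction of each field's variance from the unsmoothed
#'   component, in `[0, 1]` (default 0.3; ignored when `spatial_range = 0`).
#' @param seed Integer seed.
#' @return An n x p matrix with columns `x1 .. xp`.
#' @export
simulate_predictors <- function(geometry, p, spatial_range = 0,
                                predictor_corr = 0, nugget = 0.3, seed = 1) {
  if (p < 1) abort_config("p must be >= 1.")
  if (spatial_range < 0) abort_config("spatial_range must be >= 0.")
  if (predictor_corr < 0 || predictor_corr >= 1) {
    abort_config("predictor_corr must lie in [0, 1).")
  }
  if (nugget < 0 || nugget > 1) abort_config("nugget must lie in [0, 1].")
  n <- nrow(geometry)
  coords <- as.matrix(geometry[, c("x", "y")])
  set.seed(seed)
  noise <- matrix(rnorm(n * (p + 1)), n, p + 1)
  if (spatial_range > 0) {
    D <- as.matrix(dist(coords))
    K <- exp(-D^2 / (2 * spatial_range^2))
    smooth <- scale(K %*% noise)
    local_part <- scale(matrix(rnorm(n * (p + 1)), n, p + 1))
    noise <- sqrt(1 - nugget) * smooth + sqrt(nugget) * local_part
  }
  noise <- scale(noise)
  shared <- noise[, p + 1]
  a <- sqrt(predictor_corr)
  X <- a * shared + sqrt(1 - predictor_corr) * noise[, seq_len(p), drop = FALSE]
  X <- scale(X)
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  colnames(X) <- paste0("x", seq_len(p))
  X
}

#' Simulate the outcome from coefficient surfaces
#'
#' Linear link:
#' `y_i = beta0(u_i) + sum_j beta_j(u_i) * x_ij + e_i`,
#' `e_i ~ Normal(0, noise_sd^2)`. The nonlinear link adds a fixed, documented
#' regime term `gamma(u_i) * max(0, x_i1 - threshold)` plus an interaction
#' `interaction_coef * x_i1 * x_i2` (requires p >= 2); the regime surface
#' `gamma` defaults to a central Gaussian bump of height 1 so that tree-based
#' and linear local models can be compared reproducibly.
#'
#' @inheritParams simulate_coefficient_surface
#' @param predictors n x p predictor matrix.
#' @param surfaces List of p + 1 coefficient surfaces: intercept first, then
#'   one per predictor column. Plain numeric vectors of length n are accepted.
#' @param link `"linear"` or `"nonlinear"`.
#' @param noise_sd Outcome noise standard deviation (>= 0).
#' @param seed Integer seed for the noise draw.
#' @param nonlinear_params List with `threshold` (default 0), `gamma`
#'   (surface, default central bump of height 1) and `interaction_coef`
#'   (default 0.5).
#' @return Numeric outcome vector of length n.
#' @export
simulate_outcome <- function(geometry, predictors, surfaces,
                             link = c("linear", "nonlinear"),
                             noise_sd = 0, seed = 1,
                             nonlinear_params = list()) {
  link <- match.arg(link)
  if (noise_sd < 0) abort_config("noise_sd must be >= 0.")
  n <- nrow(geometry)
  p <- ncol(predictors)
  if (length(surfaces) != p + 1) {
    abort_config(sprintf(
      "Need %d surfaces (intercept + one per predictor); got %d.",
      p + 1, length(surfaces)))
  }
  lens <- vapply(surfaces, length, integer(1))
  if (any(lens != n)) abort_config("Every surface must have length n.")
  eta <- as.numeric(surfaces[[1]])
  for (j in seq_len(p)) {
    eta <- eta + as.numeric(surfaces[[j + 1]]) * predictors[, j]
  }
  if (link == "nonlinear") {
    if (p < 2) abort_config("Nonlinear link requires p >= 2.")
    thr <- nonlinear_params$threshold %||% 0
    gamma <- nonlinear_params$gamma %||%
      simulate_coefficient_surface(geometry, "gaussian_bump",
                                   list(base = 0, height = 1,
                                        width = diff(range(geometry$x)) / 4))
    icoef <- nonlinear_params$interaction_coef %||% 0.5
    eta <- eta + as.numeric(gamma) * pmax(0, predictors[, 1] - thr) +
      icoef * predictors[, 1] * predictors[, 2]
  }
  set.seed(seed)
  eta + rnorm(n, 0, noise_sd)
}

#' Named synthetic study scenarios
#'
#' One-call builders for the recurring simulation designs used throughout the
#' package's tests and examples, each an areal dataset with fully known local
#' coefficient structure:
#' \describe{
#'   \item{homogeneous}{p = 2, constant surfaces (1, 0.8, -0.5): a global
#'     linear model is the truth.}
#'   \item{gradient}{p = 2; the first slope runs 0 to 2 west-east, the second
#'     1 to -1 south-north: smooth spatial non-stationarity a GW-OLS should
#'     recover.}
#'   \item{two_regime}{p = 2; the first predictor drives the outcome only in
#'     the western half (slope 1.2), the second only in the eastern half:
#'     a step change in variable importance a GW-RF should localize.}
#'   \item{nonlinear}{p = 6 (mirroring a six-risk-factor design) with gradient
#'     and bump surfaces on the first two slopes plus the nonlinear link's
#'     threshold and interaction terms: spatial heterogeneity and
#'     non-additivity together.}
#' }
#' Defaults (noise_sd 0.5, spatial_range 3, predictor_corr 0.4, jitter 0.3)
#' are the package's fixed reference conditions; see the methods vignette.
#'
#' @param type Scenario name (see Details).
#' @param n_side Lattice side (default 20, i.e. n = 400).
#' @param noise_sd Outcome noise standard deviation.
#' @param spatial_range Predictor autocorrelation length-scale.
#' @param predictor_corr Target pairwise predictor correlation.
#' @param jitter Lattice jitter fraction.
#' @param seed Integer seed controlling geometry, predictors and noise.
#' @return A list with `frame` (an [as_area_frame()] with outcome `y_outcome`),
#'   `surfaces` (the true coefficient surfaces, intercept first), `geometry`,
#'   and the scenario settings.
#' @export
#' @examples
#' sc <- synth_scenario("gradient", n_side = 8, seed = 7)
#' sc$frame
synth_scenario <- function(type = c("homogeneous", "gradient", "two_regime",
                                    "nonlinear"),
                           n_side = 20, noise_sd = 0.5, spatial_range = 3,
                           predictor_corr = 0.4, jitter = 0.3, seed = 1) {
  type <- match.arg(type)
  geom <- make_lattice(n_side, jitter = jitter, seed = seed)
  p <- if (type == "nonlinear") 6L else 2L
  X <- simulate_predictors(geom, p = p, spatial_range = spatial_range,
                           predictor_corr = predictor_corr,
                           seed = hash_seed(seed, 1))
  cs <- function(kind, params) simulate_coefficient_surface(geom, kind, params)
  mid_x <- mean(range(geom$x))
  surfaces <- switch(
    type,
    homogeneous = list(cs("constant", list(value = 1)),
                       cs("constant", list(value = 0.8)),
                       cs("constant", list(value = -0.5))),
    gradient = list(cs("constant", list(value = 1)),
                    cs("gradient", list(axis = "x", from = 0, to = 2)),
                    cs("gradient", list(axis = "y", from = 1, to = -1))),
    two_regime = list(cs("constant", list(value = 1)),
                      structure(1.2 * (geom$x < mid_x), kind = "step_west"),
                      structure(1.2 * (geom$x >= mid_x), kind = "step_east")),
    nonlinear = list(cs("constant", list(value = 10)),
                     cs("gradient", list(axis = "x", from = -1.5, to = 3)),
                     cs("gaussian_bump",
                        list(base = -1, height = 3, width = n_side / 4)),
                     cs("constant", list(value = 0.4)),
                     cs("constant", list(value = -0.3)),
                     cs("gradient", list(axis = "y", from = -1, to = 1)),
                     cs("constant", list(value = 0.2)))
  )
  link <- if (type == "nonlinear") "nonlinear" else "linear"
  nl_params <- if (link == "nonlinear") {
    # strong, localized regime term so the scenario's heterogeneity is
    # expressed at desk-scale sample sizes
    list(gamma = cs("gaussian_bump",
                    list(base = 0, height = 2, width = n_side / 4)))
  } else list()
  y <- simulate_outcome(geom, X, surfaces, link = link, noise_sd = noise_sd,
                        seed = hash_seed(seed, 2), nonlinear_params = nl_params)
  data <- dplyr::bind_cols(geom, tibble::as_tibble(X), y_outcome = y)
  frame <- as_area_frame(data, outcome = "y_outcome",
                         predictors = colnames(X))
  list(frame = frame, surfaces = surfaces, geometry = geom, type = type,
       n_side = n_side, noise_sd = noise_sd, spatial_range = spatial_range,
       predictor_corr = predictor_corr, jitter = jitter, link = link,
       seed = seed)
}

#' Write a synthetic scenario to disk
#'
#' Writes the generated dataset as CSV (columns `id, x, y, y_outcome,
#' x1..xp, beta0_true..betap_true`) and the generating settings as a YAML
#' config next to it.
#'
#' @param scenario A [synth_scenario()] result.
#' @param path Output CSV path; the config is written to the same path with
#'   extension `.yaml`.
#' @return Invisibly, the CSV path.
#' @export
write_synth_csv <- function(scenario, path) {
  frame <- scenario$frame
  truth <- as.data.frame(lapply(scenario$surfaces, as.numeric))
  names(truth) <- paste0("beta", seq_along(scenario$surfaces) - 1, "_true")
  out <- dplyr::bind_cols(tibble::as_tibble(frame), truth)
  write_result_csv(out, path)
  cfg <- scenario[c("type", "n_side", "noise_sd", "spatial_range",
                    "predictor_corr", "jitter", "link", "seed")]
  yaml::write_yaml(cfg, sub("\\.csv$", ".yaml", path))
  invisible(path)
}
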