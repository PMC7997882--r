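#' Pairwise Euclidean distances
#'
#' @param coords An n x 2 numeric matrix (or data frame) of planar coordinates.
#' @return A symmetric n x n distance matrix with zero diagonal.
#' @export
pairwise_distances <- function(coords) {
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || any(!is.finite(coords))) {
    abort_validation("Coordinates must be finite numeric values.")
  }
  as.matrix(dist(coords))
}

#' Adaptive kernel bandwidths
#'
#' The adaptive bandwidth at location i is the distance from i to its k-th
#' nearest *other* location, so every local model sees (roughly) the same
#' number of observations regardless of areal density. Distance ties are
#' broken by smaller index, so the result is deterministic. `k = n` is
#' accepted and capped at the farthest neighbor (k = n - 1), which together
#' with a boxcar kernel reproduces the global (all-ones) weighting.
#'
#' @param coords n x 2 planar coordinates.
#' @param k Neighbor count, `1 <= k <= n`.
#' @return Numeric vector of per-location bandwidths.
#' @export
adaptive_bandwidth <- function(coords, k) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (k < 1 || k > n) abort_config(sprintf("k must lie in [1, %d].", n))
  k_eff <- min(k, n - 1)
  D <- pairwise_distances(coords)
  vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    sort(d, method = "radix")[k_eff]
  }, numeric(1))
}

#' Kernel weight functions
#'
#' Distance-decay weights used by every geographically weighted stage:
#' \describe{
#'   \item{bisquare}{`(1 - (d/b)^2)^2` for `d < b`, else 0 — compactly
#'     supported and smooth at the origin.}
#'   \item{boxcar}{1 for `d <= b`, else 0.}
#'   \item{gaussian}{`exp(-0.5 (d/b)^2)`.}
#' }
#' The focal location (d = 0) always gets weight 1.
#'
#' @param d Nonnegative distances from the focal location.
#' @param bandwidth Positive bandwidth `b`.
#' @param family `"bisquare"`, `"boxcar"` or `"gaussian"`.
#' @return Numeric weights, same length as `d`.
#' @export
#' @examples
#' kernel_weights(c(0, 0.5, 1, 2), bandwidth = 1, family = "bisquare")
kernel_weights <- function(d, bandwidth, family = c("bisquare", "boxcar",
                                                    "gaussian")) {
  family <- match.arg(family)
  if (bandwidth <= 0) abort_config("bandwidth must be > 0.")
  switch(family,
         bisquare = ifelse(d < bandwidth, (1 - (d / bandwidth)^2)^2, 0),
         boxcar = as.numeric(d <= bandwidth),
         gaussian = exp(-0.5 * (d / bandwidth)^2))
}

#' Kernel specification
#'
#' Bundles the kernel family with its bandwidth mode. Adaptive bandwidths are
#' neighbor counts k (the per-location bandwidth is the distance to the k-th
#' nearest neighbor); fixed bandwidths are distances in coordinate units.
#'
#' @param family Kernel family (see [kernel_weights()]).
#' @param adaptive If `TRUE`, `bandwidth` is a neighbor count; otherwise a
#'   fixed distance.
#' @param bandwidth Neighbor count (adaptive) or distance (fixed); `NULL`
#'   requests automatic selection where the calling function supports it.
#' @return A `kernel_spec` list.
#' @export
kernel_spec <- function(family = "bisquare", adaptive = TRUE,
                        bandwidth = NULL) {
  family <- match.arg(family, c("bisquare", "boxcar", "gaussian"))
  if (!is.null(bandwidth)) {
    if (adaptive) {
      if (bandwidth < 1) abort_config("Adaptive bandwidth (k) must be >= 1.")
    } else if (bandwidth <= 0) {
      abort_config("Fixed bandwidth must be > 0.")
    }
  }
  structure(list(family = family, adaptive = adaptive, bandwidth = bandwidth),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat(sprintf("kernel_spec: %s, %s bandwidth = %s\n", x$family,
              if (x$adaptive) "adaptive (k)" else "fixed (distance)",
              if (is.null(x$bandwidth)) "auto" else format(x$bandwidth)))
  invisible(x)
}

# Per-location weight vector for a kernel spec given a full distance matrix.
kernel_row_weights <- function(D, i, spec, bw_vec = NULL) {
  b <- if (spec$adaptive) bw_vec[i] else spec$bandwidth
  w <- kernel_weights(D[i, ], b, spec$family)
  w[i] <- 1
  w
}

kernel_bandwidths <- function(coords, spec) {
  if (spec$adaptive) adaptive_bandwidth(coords, spec$bandwidth) else NULL
}

#' Build a spatial weight matrix
#'
#' Constructs the n x n spatial weights shared by the exploratory statistics.
#' Schemes:
#' \describe{
#'   \item{knn_binary}{`w_ij = 1` iff j is among the k nearest neighbors of i
#'     (ties broken by lower index); optionally row-standardized; the focal
#'     unit itself is included only when `include_self = TRUE` (the Gi*
#'     variant).}
#'   \item{kernel}{continuous kernel weights from a [kernel_spec()].}
#' }
#'
#' @param frame An [as_area_frame()] (or any data frame with `x`, `y`).
#' @param scheme `"knn_binary"` or `"kernel"`.
#' @param k Neighbor count for `knn_binary` (default 8, the queen-like
#'   lattice default).
#' @param kernel A [kernel_spec()] for the kernel scheme.
#' @param row_standardize Scale each row to sum to 1.
#' @param include_self Include the focal unit with weight 1 before any
#'   standardization.
#' @return A `weight_matrix` object: list with dense numeric matrix `w`,
#'   `ids`, and the construction flags.
#' @export
build_weight_matrix <- function(frame, scheme = c("knn_binary", "kernel"),
                                k = 8, kernel = NULL,
                                row_standardize = FALSE,
                                include_self = FALSE) {
  scheme <- match.arg(scheme)
  coords <- if (inherits(frame, "area_frame")) area_coords(frame)
            else as.matrix(frame[, c("x", "y")])
  ids <- if (inherits(frame, "area_frame")) area_ids(frame)
         else seq_len(nrow(frame)) - 1
  n <- nrow(coords)
  D <- pairwise_distances(coords)
  W <- matrix(0, n, n)
  if (scheme == "knn_binary") {
    if (k < 1 || k > n - 1) {
      abort_config(sprintf("k must lie in [1, %d].", n - 1))
    }
    for (i in seq_len(n)) {
      ord <- order(D[i, -i], method = "radix")
      others <- seq_len(n)[-i]
      W[i, others[ord[seq_len(k)]]] <- 1
    }
  } else {
    if (is.null(kernel)) abort_config("kernel scheme requires a kernel_spec.")
    bw <- kernel_bandwidths(coords, kernel)
    for (i in seq_len(n)) {
      W[i, ] <- kernel_row_weights(D, i, kernel, bw)
      W[i, i] <- 0
    }
  }
  if (include_self) diag(W) <- 1
  if (any(rowSums(W) == 0)) {
    abort_config("Empty neighbor set for at least one location.")
  }
  if (row_standardize) W <- W / rowSums(W)
  structure(list(w = W, ids = ids, scheme = scheme,
                 row_standardized = row_standardize,
                 include_self = include_self),
            class = "weight_matrix")
}

#' @export
print.weight_matrix <- function(x, ...) {
  cat(sprintf(
    "weight_matrix: %d x %d (%s)%s%s, %d nonzero\n",
    nrow(x$w), ncol(x$w), x$scheme,
    if (x$row_standardized) ", row-standardized" else "",
    if (x$include_self) ", self-included" else "",
    sum(x$w != 0)))
  invisible(x)
}

#' Export a weight matrix as an edge list
#'
#' Writes the nonzero weights as a three-column (`i`, `j`, `w`) text file
#' keyed by the unit ids.
#'
#' @param W A [build_weight_matrix()] object.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_edge_list <- function(W, path) {
  nz <- which(W$w != 0, arr.ind = TRUE)
  edges <- tibble::tibble(i = W$ids[nz[, 1]], j = W$ids[nz[, 2]],
                          w = W$w[nz]) |>
    dplyr::arrange(.data$i, .data$j)
  write_result_csv(edges, path)
}
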