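#' Construct an areal data frame
#'
#' An `area_frame` is the container every stage of the package consumes: one
#' row per areal unit (e.g. a county) carrying a unique id, planar centroid
#' coordinates, a continuous outcome (such as disease prevalence in percent)
#' and one or more continuous predictors. It is an ordinary tibble with
#' recorded column roles, so it pipes through dplyr verbs; the roles travel
#' with the object via attributes.
#'
#' Coordinates are treated as planar: all distances are Euclidean in the
#' supplied units. Longitude/latitude data must be projected upstream (the
#' pipeline offers an equirectangular fallback with a warning).
#'
#' @param data A data frame with one row per areal unit.
#' @param outcome Name of the outcome column.
#' @param predictors Character vector of predictor column names. Defaults to
#'   all numeric columns other than the id, coordinate and outcome columns.
#' @param id Name of the unique-id column (default `"id"`).
#' @param coords Length-2 character vector naming the planar coordinate
#'   columns (default `c("x", "y")`).
#'
#' @return A tibble of class `area_frame`.
#' @export
#' @examples
#' d <- tibble::tibble(id = 1:9, x = rep(0:2, 3), y = rep(0:2, each = 3),
#'                     prev = rnorm(9, 10), pov = rnorm(9))
#' af <- as_area_frame(d, outcome = "prev")
#' predictor_names(af)
as_area_frame <- function(data, outcome, predictors = NULL,
                          id = "id", coords = c("x", "y")) {
  data <- tibble::as_tibble(data)
  need <- c(id, coords, outcome)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    abort_schema(paste0("Missing required column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  if (is.null(predictors)) {
    numeric_cols <- names(data)[vapply(data, is.numeric, logical(1))]
    predictors <- setdiff(numeric_cols, c(id, coords, outcome))
  }
  missing_preds <- setdiff(predictors, names(data))
  if (length(missing_preds) > 0) {
    abort_schema(paste0("Unknown predictor column(s): ",
                        paste(missing_preds, collapse = ", ")))
  }
  if (length(predictors) == 0) {
    abort_schema("At least one predictor column is required.")
  }
  if (anyDuplicated(data[[id]])) {
    dups <- unique(data[[id]][duplicated(data[[id]])])
    abort_schema(paste0("Duplicate id(s): ",
                        paste(head(dups, 5), collapse = ", ")))
  }
  for (col in c(coords, outcome, predictors)) {
    if (!is.numeric(data[[col]])) {
      abort_schema(paste0("Column '", col, "' must be numeric."))
    }
    if (any(!is.finite(data[[col]]))) {
      abort_validation(paste0("Column '", col, "' contains non-finite values."))
    }
  }
  structure(
    data,
    class = c("area_frame", class(tibble::tibble())),
    gw_roles = list(id = id, coords = coords, outcome = outcome,
                    predictors = predictors)
  )
}

gw_roles <- function(frame) {
  roles <- attr(frame, "gw_roles")
  if (is.null(roles)) {
    abort_validation("Input is not an area_frame; use as_area_frame() first.")
  }
  roles
}

#' Accessors for an area frame
#'
#' @param frame An [as_area_frame()] object.
#' @return `area_ids()` the id vector; `area_coords()` an n x 2 numeric matrix;
#'   `area_outcome()` the outcome vector; `area_predictors()` an n x p numeric
#'   matrix with predictor names; `predictor_names()` / `outcome_name()` the
#'   recorded column roles.
#' @export
area_ids <- function(frame) frame[[gw_roles(frame)$id]]

#' @rdname area_ids
#' @export
area_coords <- function(frame) {
  roles <- gw_roles(frame)
  m <- as.matrix(frame[, roles$coords])
  dimnames(m) <- list(NULL, c("x", "y"))
  m
}

#' @rdname area_ids
#' @export
area_outcome <- function(frame) frame[[gw_roles(frame)$outcome]]

#' @rdname area_ids
#' @export
area_predictors <- function(frame) {
  roles <- gw_roles(frame)
  m <- as.matrix(frame[, roles$predictors])
  colnames(m) <- roles$predictors
  m
}

#' @rdname area_ids
#' @export
predictor_names <- function(frame) gw_roles(frame)$predictors

#' @rdname area_ids
#' @export
outcome_name <- function(frame) gw_roles(frame)$outcome

# Check a frame is usable for regression stages: n >= p + 2.
check_regression_size <- function(frame) {
  n <- nrow(frame)
  p <- length(predictor_names(frame))
  if (n < p + 2) {
    abort_validation(sprintf(
      "Need at least p + 2 = %d rows for regression stages; got %d.", p + 2, n))
  }
  invisible(frame)
}

#' Read an areal table from CSV or GeoJSON
#'
#' Reads a delimited table (CSV with header) or a GeoJSON FeatureCollection of
#' Point or Polygon features into a validated [as_area_frame()]. For polygons,
#' the centroid is computed as the arithmetic mean of the outer-ring vertices
#' (the closing vertex, when repeated, is dropped first); this simple rule is
#' documented behaviour, not an area-weighted centroid. Rows with missing
#' outcome or predictor values are dropped with a message reporting the count.
#'
#' @param path Path to a `.csv` or `.geojson`/`.json` file.
#' @inheritParams as_area_frame
#' @return An `area_frame` tibble.
#' @export
read_area_table <- function(path, outcome, predictors = NULL,
                            id = "id", coords = c("x", "y")) {
  if (!file.exists(path)) abort_schema(paste0("File not found: ", path))
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    data <- read_geojson_table(path, coords)
  } else {
    data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  keep_cols <- c(outcome, predictors)
  keep_cols <- keep_cols[keep_cols %in% names(data)]
  ok <- complete.cases(data[, keep_cols, drop = FALSE])
  if (any(!ok)) {
    inform(sprintf("Dropping %d row(s) with missing outcome/predictor values.",
                   sum(!ok)))
    data <- data[ok, , drop = FALSE]
  }
  if (nrow(data) == 0) abort_schema("No complete rows left after validation.")
  as_area_frame(data, outcome = outcome, predictors = predictors,
                id = id, coords = coords)
}

# Minimal GeoJSON FeatureCollection reader (Point / Polygon). Properties become
# columns; geometry becomes the coordinate columns.
read_geojson_table <- function(path, coords = c("x", "y")) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) {
    abort_schema("GeoJSON input must be a FeatureCollection.")
  }
  feats <- gj$features
  rows <- purrr::map(feats, function(f) {
    geom <- f$geometry
    cen <- geojson_centroid(geom)
    props <- purrr::map(f$properties, function(v) if (is.null(v)) NA else v)
    tibble::as_tibble(c(props, setNames(as.list(cen), coords)))
  })
  dplyr::bind_rows(rows)
}

geojson_centroid <- function(geom) {
  if (identical(geom$type, "Point")) {
    return(c(geom$coordinates[[1]], geom$coordinates[[2]]))
  }
  if (identical(geom$type, "Polygon")) {
    ring <- geom$coordinates[[1]]
    pts <- do.call(rbind, purrr::map(ring, ~ c(.x[[1]], .x[[2]])))
    if (nrow(pts) > 1 && all(pts[1, ] == pts[nrow(pts), ])) {
      pts <- pts[-nrow(pts), , drop = FALSE]
    }
    return(colMeans(pts))
  }
  abort_schema(paste0("Unsupported GeoJSON geometry type: ", geom$type))
}

#' @export
print.area_frame <- function(x, ...) {
  roles <- attr(x, "gw_roles")
  cat(sprintf("# area_frame: %d units, outcome '%s', %d predictor(s)\n",
              nrow(x), roles$outcome, length(roles$predictors)))
  NextMethod()
}
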