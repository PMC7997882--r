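#' Map a per-location surface over areal-unit centroids
#'
#' Generic point-map helper used by the autoplot methods: centroids colored
#' by a per-location value.
#'
#' @param frame An [as_area_frame()] (supplies the coordinates).
#' @param values Per-location numeric or factor vector (input order).
#' @param title,legend Plot and legend titles.
#' @return A ggplot object.
#' @export
plot_surface <- function(frame, values, title = NULL, legend = "value") {
  coords <- area_coords(frame)
  df <- tibble::tibble(x = coords[, 1], y = coords[, 2], value = values)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                         colour = .data$value)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = title, colour = legend, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
  if (is.numeric(values)) gg <- gg + ggplot2::scale_colour_viridis_c()
  gg
}

#' @describeIn fit_gwols Map of one local coefficient surface (default: the
#'   first slope).
#' @param term Coefficient name to map.
#' @export
autoplot.gwols_fit <- function(object, term = NULL, ...) {
  term <- term %||% object$coef_names[min(2, length(object$coef_names))]
  j <- match(term, object$coef_names)
  if (is.na(j)) abort_config(paste0("Unknown term: ", term))
  plot_surface(object$frame, object$beta[, j],
               title = paste0("GW-OLS local coefficient: ", term),
               legend = "estimate")
}

#' @describeIn fit_gwrf Map of one predictor's local %IncMSE surface
#'   (default: the first predictor).
#' @param predictor Predictor name to map.
#' @export
autoplot.gwrf_fit <- function(object, predictor = NULL, ...) {
  predictor <- predictor %||% colnames(object$incmse)[1]
  j <- match(predictor, colnames(object$incmse))
  if (is.na(j)) abort_config(paste0("Unknown predictor: ", predictor))
  plot_surface(object$frame, object$incmse[, j],
               title = paste0("GW-RF local %IncMSE: ", predictor),
               legend = "%IncMSE")
}

#' @describeIn compare_models Observed-vs-predicted 1:1 panels per model.
#' @param object An `eval_report`.
#' @export
autoplot.eval_report <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::facet_wrap(~model) +
    ggplot2::labs(x = "Observed", y = "Predicted",
                  title = "Held-out observed vs predicted (1:1 line)") +
    ggplot2::theme_minimal()
}

#' Hotspot class map
#'
#' @param frame The [as_area_frame()] the hotspot result came from.
#' @param hotspots A [getis_ord_gi_star()] result.
#' @return A ggplot object.
#' @export
plot_hotspots <- function(frame, hotspots) {
  lv <- c("cold99", "cold95", "cold90", "ns", "hot90", "hot95", "hot99")
  cls <- factor(hotspots$class, levels = lv)
  coords <- area_coords(frame)
  df <- tibble::tibble(x = coords[, 1], y = coords[, 2], class = cls)
  pal <- c(cold99 = "#2166ac", cold95 = "#67a9cf", cold90 = "#d1e5f0",
           ns = "grey85", hot90 = "#fddbc7", hot95 = "#ef8a62",
           hot99 = "#b2182b")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$class)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(values = pal, drop = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Getis-Ord Gi* hotspot classes", colour = "class",
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
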