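# ggplot2 views of the result objects.

#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_point geom_step
#'   geom_abline geom_col facet_wrap labs scale_fill_manual scale_y_log10
#'   coord_equal theme_minimal position_dodge
#' @export
ggplot2::autoplot

#' Plot an empirical CCDF on a log-linear scale
#'
#' An exponential-tailed count law appears as a straight line.
#'
#' @param values Numeric vector of counts, or a tibble from [ccdf()].
#' @param var_label Axis label for the variable.
#' @return A ggplot.
#' @export
plot_ccdf <- function(values, var_label = "activity count") {
  df <- if (is.data.frame(values)) values else ccdf(values)
  df <- df[df$p > 0, , drop = FALSE]
  ggplot(df, aes(x = .data$x, y = .data$p)) +
    geom_step() +
    scale_y_log10() +
    labs(x = var_label, y = "P(X > x)") +
    theme_minimal()
}

#' Map an AMOEBA cluster solution
#'
#' Tile map of cluster membership over the areal partition.
#'
#' @param object An `amoeba_clusters` object.
#' @param areas Area tibble with `id`, `centre_x`, `centre_y` (e.g.
#'   `bundle$areas`).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot amoeba_clusters
#' @export
autoplot.amoeba_clusters <- function(object, areas, ...) {
  df <- tidy(object) %>%
    inner_join(areas %>% select("id", "centre_x", "centre_y"),
               by = c(area_id = "id"))
  ggplot(df, aes(x = .data$centre_x, y = .data$centre_y,
                 fill = .data$cluster_type)) +
    geom_tile() +
    scale_fill_manual(values = c(high = "#b2182b", outside = "grey85",
                                 low = "#2166ac")) +
    coord_equal() +
    labs(x = "x (m)", y = "y (m)", fill = "cluster",
         title = "Clusters of high / low non-commuting rate") +
    theme_minimal()
}

#' Predicted vs observed non-commuting counts
#'
#' @param object A `purpose_cv` object.
#' @param ... Unused.
#' @return A ggplot, one panel per model.
#' @method autoplot purpose_cv
#' @export
autoplot.purpose_cv <- function(object, ...) {
  ggplot(object$predictions, aes(x = .data$actual, y = .data$predicted)) +
    geom_point(alpha = 0.3, size = 0.6) +
    geom_abline(slope = 1, intercept = 0, colour = "red", linetype = 2) +
    facet_wrap(~model) +
    labs(x = "observed non-commuting count", y = "predicted") +
    theme_minimal()
}

#' Exposure means by purpose and pollutant
#'
#' @param object An `exposure_summary` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot exposure_summary
#' @export
autoplot.exposure_summary <- function(object, ...) {
  s <- object$summary
  df <- tibble(
    pollutant = rep(c("PM10", "PM2.5"), each = 2),
    purpose = rep(c("non-commuting", "commuting"), 2),
    mean = c(s$mean_pm10_non, s$mean_pm10_com, s$mean_pm25_non, s$mean_pm25_com)
  )
  ggplot(df, aes(x = .data$pollutant, y = .data$mean, fill = .data$purpose)) +
    geom_col(position = position_dodge()) +
    labs(y = "activity-weighted mean exposure (µg/m³)", x = NULL,
         fill = NULL) +
    theme_minimal()
}
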