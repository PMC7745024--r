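#' Plot a gridded concentration field
#'
#' @param object A `grid_field`.
#' @param ... Unused.
#' @return A ggplot raster of the field (µg/m³), masked cells blank.
#' @method autoplot grid_field
#' @export
autoplot.grid_field <- function(object, ...) {
  df <- as_tibble.grid_field(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$u / 1000, y = .data$v / 1000,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = expression(PM[2.5] ~ (mu * g / m^3))) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "easting (km)", y = "northing (km)") +
    ggplot2::theme_minimal()
}

#' Residual diagnostics panel
#'
#' Observed-vs-calibrated scatter with the 1:1 line, or a normal
#' probability plot of the residuals.
#'
#' @param object A `residual_report`.
#' @param type `"scatter"` or `"qq"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot residual_report
#' @export
autoplot.residual_report <- function(object, type = c("scatter", "qq"), ...) {
  type <- match.arg(type)
  if (type == "scatter") {
    ggplot2::ggplot(object$residuals,
                    ggplot2::aes(x = .data$calibrated, y = .data$observed)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                           colour = "grey50") +
      ggplot2::geom_point(alpha = 0.7) +
      ggplot2::labs(x = "calibrated PM2.5 (ug/m3)",
                    y = "observed PM2.5 (ug/m3)") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$normality,
                    ggplot2::aes(x = .data$theoretical, y = .data$residual)) +
      ggplot2::geom_point() +
      ggplot2::geom_qq_line(ggplot2::aes(sample = .data$residual),
                            inherit.aes = FALSE, linetype = 2,
                            colour = "grey50") +
      ggplot2::labs(x = "standard normal quantile",
                    y = "ordered residual (ug/m3)") +
      ggplot2::theme_minimal()
  }
}

#' Map of the spatially varying calibration coefficients
#'
#' One panel per coefficient (intercept and slopes) at the training anchors.
#'
#' @param object A `spatial_calibration`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot spatial_calibration
#' @export
autoplot.spatial_calibration <- function(object, ...) {
  df <- tidy.spatial_calibration(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$u / 1000, y = .data$v / 1000,
                                   colour = .data$estimate)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~term, scales = "free") +
    ggplot2::scale_colour_viridis_c(name = "coefficient") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "easting (km)", y = "northing (km)") +
    ggplot2::theme_minimal()
}

#' Histogram of a network's PM2.5 readings in 10 µg/m³ bins
#'
#' @param obs An [observation_set()].
#' @return A ggplot column chart of [distribution_summary()] counts.
#' @export
plot_distribution <- function(obs) {
  s <- distribution_summary(obs)
  ggplot2::ggplot(s$histogram,
                  ggplot2::aes(x = (.data$bin_lower + .data$bin_upper) / 2,
                               y = .data$count)) +
    ggplot2::geom_col(width = 9, fill = "steelblue") +
    ggplot2::labs(x = "PM2.5 (ug/m3)", y = "count") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
#' @importFrom tibble as_tibble
NULL
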