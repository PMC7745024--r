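#' Residual diagnostics for a calibration at the collocated stations
#'
#' Residuals are `e_i = Y_i - Y'_i`: the regulatory observation minus the
#' calibrated low-cost value at the paired location. Reports the RMSE
#' `sqrt(mean(e_i^2))`, the coefficient of determination
#' `R^2 = 1 - SS_res / SS_tot` (total sum of squares about the mean of `Y`),
#' and ordered residual / standard-normal quantile pairs at plotting
#' positions `(i - 0.5) / n` for normal probability plots.
#'
#' @param pairs Non-empty `collocated_pairs`.
#' @param calibrated_y Calibrated PM2.5 at each pair, aligned one-to-one
#'   with `pairs` (µg/m³).
#' @return An object of class `residual_report`: `residuals` (tibble with
#'   `station_id`, `observed`, `calibrated`, `residual`), `rmse`,
#'   `r_squared`, `n`, and `normality` (tibble `theoretical`, `residual`).
#' @export
residual_report <- function(pairs, calibrated_y) {
  stopifnot(inherits(pairs, "collocated_pairs"))
  if (length(calibrated_y) != nrow(pairs)) {
    abort_pm(sprintf("calibrated_y has length %d but there are %d pairs.",
                     length(calibrated_y), nrow(pairs)), "alignment_error")
  }
  e <- pairs$y - calibrated_y
  n <- length(e)
  ord <- sort(e)
  structure(
    list(
      residuals = tibble::tibble(
        station_id = pairs$station_id,
        observed = pairs$y,
        calibrated = calibrated_y,
        residual = e
      ),
      rmse = sqrt(mean(e^2)),
      r_squared = 1 - sum(e^2) / sum((pairs$y - mean(pairs$y))^2),
      n = n,
      normality = tibble::tibble(
        theoretical = stats::qnorm((seq_len(n) - 0.5) / n),
        residual = ord
      )
    ),
    class = "residual_report"
  )
}

#' @export
print.residual_report <- function(x, ...) {
  cat(sprintf("<residual_report: n = %d, RMSE = %.3f ug/m3, R^2 = %.3f>\n",
              x$n, x$rmse, x$r_squared))
  cat(sprintf("  residual range: [%.2f, %.2f] ug/m3\n",
              min(x$residuals$residual), max(x$residuals$residual)))
  invisible(x)
}

#' @rdname residual_report
#' @param x A `residual_report`.
#' @param ... Unused.
#' @method glance residual_report
#' @export
glance.residual_report <- function(x, ...) {
  tibble::tibble(rmse = x$rmse, r_squared = x$r_squared, n = x$n,
                 min_residual = min(x$residuals$residual),
                 max_residual = max(x$residuals$residual))
}

#' Distributional summary of a network's PM2.5 readings
#'
#' Mean, standard deviation and variance (population denominator `n`) plus
#' a histogram over fixed 10 µg/m³ bins `[0, 10), [10, 20), ...`, the
#' granularity used for comparing raw and calibrated sensor distributions
#' against the regulatory network.
#'
#' @param obs Non-empty [observation_set()] (or any table with `pm25`).
#' @return A list: `mean`, `sd`, `variance` (population), and `histogram`
#'   (tibble `bin_lower`, `bin_upper`, `count`).
#' @export
distribution_summary <- function(obs) {
  if (nrow(obs) == 0) {
    abort_pm("empty observation set.", "empty_input_error")
  }
  x <- obs$pm25
  n <- length(x)
  m <- mean(x)
  v <- sum((x - m)^2) / n
  # half-open bins [0,10), [10,20), ...; the top break always sits strictly
  # above the maximum so every value falls inside a bin
  upper <- (floor(max(x) / 10) + 1) * 10
  breaks <- seq(0, upper, by = 10)
  counts <- as.integer(table(cut(x, breaks = breaks, right = FALSE)))
  list(
    mean = m,
    sd = sqrt(v),
    variance = v,
    histogram = tibble::tibble(
      bin_lower = breaks[-length(breaks)],
      bin_upper = breaks[-1],
      count = counts
    )
  )
}

#' Pearson correlation between two aligned value lists
#'
#' @param a,b Numeric vectors of equal length `>= 3`, each with nonzero
#'   variance.
#' @return Pearson's r in `[-1, 1]`.
#' @export
pearson_correlation <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3) {
    abort_pm("inputs must have equal length >= 3.", "value_error")
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    abort_pm("correlation undefined: zero variance input.",
             "undefined_correlation_error")
  }
  stats::cor(a, b)
}

#' Write a residual report to CSV (per-station rows) and JSON (summary)
#'
#' @param report A `residual_report`.
#' @param path_csv,path_json Output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_residual_report <- function(report, path_csv = NULL, path_json = NULL) {
  stopifnot(inherits(report, "residual_report"))
  if (!is.null(path_csv)) {
    readr::write_csv(report$residuals, path_csv, progress = FALSE)
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(
      list(rmse = report$rmse, r_squared = report$r_squared, n = report$n),
      path_json, auto_unbox = TRUE, digits = NA)
  }
  invisible(c(path_csv, path_json))
}
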