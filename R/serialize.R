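#' Serialize a fitted calibration to a JSON document
#'
#' The document holds the model kind, coefficients (global) or the
#' bandwidth, per-anchor coefficient map and full training-pair table
#' (spatial, so the model can be re-solved at any coordinate after
#' reloading), plus provenance (package version, seed/config echo supplied
#' by the caller).
#'
#' @param model A `global_calibration` or `spatial_calibration`.
#' @param path Output path.
#' @param provenance Optional named list echoed into the document.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, provenance = list()) {
  doc <- list(
    package = "pmcalibrate",
    version = as.character(utils::packageVersion("pmcalibrate")),
    provenance = provenance
  )
  if (inherits(model, "global_calibration")) {
    doc$kind <- "global"
    doc$beta <- as.list(model$beta)
    doc$n_train <- model$n_train
    doc$B <- model$B
    doc$covariates <- model$covariates
    doc$r_squared <- model$r_squared
    doc$rmse <- model$rmse
  } else if (inherits(model, "spatial_calibration")) {
    doc$kind <- "spatial"
    doc$bandwidth <- model$bandwidth
    doc$B <- model$B
    doc$covariates <- model$covariates
    doc$ridge_epsilon <- model$ridge_epsilon
    doc$n_ridge <- model$n_ridge
    doc$r_squared <- model$r_squared
    doc$rmse <- model$rmse
    doc$local_coefficients <- model$local_coefficients
    doc$training_pairs <- tibble::as_tibble(model$pairs)
    doc$pairs_attrs <- list(
      max_distance = as.character(attr(model$pairs, "max_distance")),
      n_excluded = attr(model$pairs, "n_excluded"),
      B = attr(model$pairs, "B"),
      covariates = attr(model$pairs, "covariates")
    )
  } else {
    abort_pm("not a calibration model.", "value_error")
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Load a calibration model written by [write_model()]
#'
#' @param path JSON path.
#' @return A `global_calibration` or `spatial_calibration`.
#' @export
read_model <- function(path) {
  doc <- jsonlite::fromJSON(path)
  if (identical(doc$kind, "global")) {
    beta <- unlist(doc$beta)
    return(structure(
      list(beta = beta, n_train = doc$n_train, B = doc$B,
           covariates = doc$covariates,
           fitted = NULL, r_squared = doc$r_squared, rmse = doc$rmse),
      class = "global_calibration"
    ))
  }
  if (identical(doc$kind, "spatial")) {
    pa <- doc$pairs_attrs
    pairs <- new_collocated_pairs(
      tibble::as_tibble(doc$training_pairs),
      max_distance = if (is.null(pa$max_distance)) Inf else as.numeric(pa$max_distance),
      n_excluded = as.integer(pa$n_excluded),
      B = as.integer(pa$B),
      covariates = pa$covariates
    )
    return(structure(
      list(bandwidth = doc$bandwidth,
           local_coefficients = tibble::as_tibble(doc$local_coefficients),
           pairs = pairs, B = doc$B, covariates = doc$covariates,
           ridge_epsilon = doc$ridge_epsilon, n_ridge = doc$n_ridge,
           bandwidth_cv = NULL, fitted = NULL,
           r_squared = doc$r_squared, rmse = doc$rmse),
      class = "spatial_calibration"
    ))
  }
  abort_pm("unrecognized model document.", "io_error")
}
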