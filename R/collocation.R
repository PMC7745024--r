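#' Pair each regulatory station with its nearest low-cost sensor
#'
#' Station-centric nearest-neighbour matching: every station contributes one
#' calibration pair `(y = station PM2.5, x1 = nearest sensor PM2.5)` anchored
#' at the station's coordinate. Distances are planar Euclidean in meters.
#' Ties are broken by the lexicographically smallest sensor id.
#'
#' @param stations A regulatory [observation_set()].
#' @param sensors A low-cost [observation_set()].
#' @param covariates Optional character vector of additional sensor
#'   covariate columns (e.g. `"rh"`) to carry into the design as `x2`, ...;
#'   sensors missing a requested covariate drop their pair (counted).
#' @return A tibble of class `collocated_pairs` with columns `station_id`,
#'   `sensor_id`, `distance`, `y`, `x1` (+ `x2`, ... for covariates), `u`,
#'   `v`, and attributes `max_distance` (`Inf` until filtered), `n_excluded`
#'   and `B` (number of covariates).
#' @export
collocate_nearest <- function(stations, sensors, covariates = character()) {
  if (!inherits(stations, "obs_set") || nrow(stations) == 0) {
    abort_pm("`stations` must be a non-empty observation set.", "empty_input_error")
  }
  if (!inherits(sensors, "obs_set") || nrow(sensors) == 0) {
    abort_pm("`sensors` must be a non-empty observation set.", "empty_input_error")
  }
  missing_cov <- setdiff(covariates, names(sensors))
  if (length(missing_cov) > 0) {
    abort_pm(paste0("sensor set lacks covariate column(s): ",
                    paste(missing_cov, collapse = ", ")),
             "configuration_error")
  }

  # order sensors by id once so which.min's first-hit is the lexicographic
  # tie-break
  sidx <- order(sensors$id)
  su <- sensors$u[sidx]
  sv <- sensors$v[sidx]

  nn <- purrr::map(seq_len(nrow(stations)), function(i) {
    d2 <- (su - stations$u[i])^2 + (sv - stations$v[i])^2
    j <- which.min(d2)
    list(j = sidx[j], distance = sqrt(d2[j]))
  })

  j <- purrr::map_int(nn, "j")
  pairs <- tibble::tibble(
    station_id = stations$id,
    sensor_id = sensors$id[j],
    distance = purrr::map_dbl(nn, "distance"),
    y = stations$pm25,
    x1 = sensors$pm25[j],
    u = stations$u,
    v = stations$v
  )
  if (length(covariates) > 0) {
    for (k in seq_along(covariates)) {
      pairs[[paste0("x", k + 1)]] <- as.numeric(sensors[[covariates[k]]][j])
    }
    # move covariates before anchors, matching the serialization layout
    pairs <- pairs[, c("station_id", "sensor_id", "distance", "y",
                       paste0("x", seq_len(length(covariates) + 1)), "u", "v")]
    ok <- stats::complete.cases(pairs)
    if (any(!ok)) {
      pm_log(sprintf("dropped %d pair(s) with missing covariate value(s)", sum(!ok)))
      pairs <- pairs[ok, , drop = FALSE]
    }
  }
  new_collocated_pairs(pairs, max_distance = Inf, n_excluded = 0L,
                       B = length(covariates) + 1L,
                       covariates = c("pm25", covariates))
}

new_collocated_pairs <- function(pairs, max_distance, n_excluded, B,
                                 covariates) {
  structure(
    tibble::as_tibble(pairs),
    max_distance = max_distance,
    n_excluded = n_excluded,
    B = B,
    covariates = covariates,
    class = c("collocated_pairs", class(tibble::tibble()))
  )
}

#' Drop collocated pairs beyond a separation threshold
#'
#' A pair whose station–sensor distance exceeds `max_distance` is not a
#' credible collocation and is excluded from the calibration training set.
#' The default threshold is 2 km. Idempotent.
#'
#' @param pairs A `collocated_pairs` tibble.
#' @param max_distance Threshold in meters (> 0); default 2000.
#' @return Filtered `collocated_pairs` with `n_excluded` updated (cumulative
#'   across repeated filtering).
#' @export
filter_pairs <- function(pairs, max_distance = 2000) {
  stopifnot(inherits(pairs, "collocated_pairs"))
  check_number(max_distance, "max_distance", finite = FALSE)
  if (max_distance <= 0) {
    abort_pm("`max_distance` must be > 0.", "value_error")
  }
  keep <- pairs$distance <= max_distance
  n_excluded <- sum(!keep) + (attr(pairs, "n_excluded") %||% 0L)
  out <- pairs[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    abort_pm("no collocated pairs remain after distance filtering.",
             "empty_training_set_error")
  }
  if (any(!keep)) {
    pm_log(sprintf("excluded %d pair(s) with separation > %g m",
                   sum(!keep), max_distance))
  }
  new_collocated_pairs(out, max_distance = max_distance,
                       n_excluded = as.integer(n_excluded),
                       B = attr(pairs, "B"),
                       covariates = attr(pairs, "covariates"))
}

#' Mean station–sensor separation of collocated pairs
#'
#' @param pairs Non-empty `collocated_pairs`.
#' @return Arithmetic mean pair distance in meters.
#' @export
mean_pair_distance <- function(pairs) {
  stopifnot(inherits(pairs, "collocated_pairs"))
  if (nrow(pairs) == 0) {
    abort_pm("no pairs.", "empty_input_error")
  }
  mean(pairs$distance)
}

#' Write collocated pairs to an audit CSV
#'
#' Columns: `station_id, sensor_id, distance_m, y, x1..xB, u, v`.
#' @param pairs A `collocated_pairs` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  stopifnot(inherits(pairs, "collocated_pairs"))
  out <- tibble::as_tibble(pairs)
  names(out)[names(out) == "distance"] <- "distance_m"
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @export
print.collocated_pairs <- function(x, ...) {
  cat(sprintf("<collocated_pairs: %d pairs, B = %d, max_distance = %s m, %d excluded>\n",
              nrow(x), attr(x, "B"), format(attr(x, "max_distance")),
              attr(x, "n_excluded")))
  NextMethod()
}

# design matrix (with intercept column) and response from pairs
design_matrix <- function(pairs) {
  B <- attr(pairs, "B")
  X <- cbind(1, as.matrix(pairs[, paste0("x", seq_len(B)), drop = FALSE]))
  colnames(X) <- c("(Intercept)", paste0("x", seq_len(B)))
  X
}
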