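#' Build a validated set of point observations
#'
#' An observation set is the package's basic container: one network
#' (low-cost sensors or regulatory stations) at one time slice, as a tibble
#' with planar coordinates in meters and PM2.5 in µg/m³. Records with a
#' missing or negative PM2.5, or non-finite coordinates, are dropped and
#' counted; the drop count is kept as the `n_dropped` attribute and logged.
#'
#' @param data A data frame with columns `id`, `u`, `v`, `pm25`; any further
#'   columns (e.g. `rh`, `temp`, `timestamp`) are carried through as
#'   covariates/metadata.
#' @param network_kind Either `"low_cost"` or `"regulatory"`.
#' @param crs_note Free-text description of the projection that produced
#'   `(u, v)`.
#' @return A tibble of class `obs_set` with attributes `network_kind`,
#'   `crs_note` and `n_dropped`. Ids are unique; `pm25 >= 0`; `u`, `v`
#'   finite, in meters.
#' @examples
#' observation_set(
#'   tibble::tibble(id = c("a", "b"), u = c(0, 100), v = c(0, 0),
#'                  pm25 = c(12, 30)),
#'   network_kind = "low_cost"
#' )
#' @export
observation_set <- function(data, network_kind = c("low_cost", "regulatory"),
                            crs_note = "") {
  network_kind <- match.arg(network_kind)
  data <- tibble::as_tibble(data)
  required <- c("id", "u", "v", "pm25")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort_pm(
      paste0("observation data lacks column(s): ",
             paste(missing_cols, collapse = ", ")),
      "configuration_error"
    )
  }
  if (nrow(data) == 0) {
    abort_pm("observation data has no rows.", "empty_input_error")
  }
  data$id <- as.character(data$id)
  data$u <- as.numeric(data$u)
  data$v <- as.numeric(data$v)
  data$pm25 <- as.numeric(data$pm25)
  keep <- !is.na(data$pm25) & data$pm25 >= 0 &
    is.finite(data$u) & is.finite(data$v) & !is.na(data$id)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    pm_log(sprintf("dropped %d invalid record(s) (missing/negative pm25 or non-finite coordinates)",
                   n_dropped))
  }
  data <- data[keep, , drop = FALSE]
  if (nrow(data) == 0) {
    abort_pm("all records were invalid.", "empty_input_error")
  }
  if (anyDuplicated(data$id)) {
    abort_pm("observation ids must be unique within a set.", "value_error")
  }
  structure(
    data,
    class = c("obs_set", class(tibble::tibble()))
  ) |>
    set_obs_attrs(network_kind = network_kind, crs_note = crs_note,
                  n_dropped = n_dropped)
}

set_obs_attrs <- function(x, network_kind, crs_note, n_dropped) {
  attr(x, "network_kind") <- network_kind
  attr(x, "crs_note") <- crs_note
  attr(x, "n_dropped") <- n_dropped
  x
}

#' Covariate columns of an observation set
#'
#' Everything that is neither a coordinate, the id, the PM2.5 reading, nor
#' the timestamp is treated as a covariate (e.g. `rh`, `temp`).
#' @param obs An `obs_set`.
#' @return Character vector of covariate column names.
#' @export
covariate_names <- function(obs) {
  setdiff(names(obs), c("id", "u", "v", "pm25", "timestamp"))
}

#' Read point observations from CSV or JSON
#'
#' Reads a flat table of sensor or station records, renames columns through
#' `column_map`, projects longitude/latitude to planar meters with
#' [project_lonlat()] (unless the input already carries `u`/`v` columns, in
#' which case they are used as-is), and validates via [observation_set()].
#'
#' @param path Input file.
#' @param network_kind `"low_cost"` or `"regulatory"`.
#' @param format `"csv"` or `"json"` (JSON: an array of flat objects).
#' @param column_map Named character vector mapping the canonical names
#'   `id`, `lon`, `lat`, `pm25` (and optionally `rh`, `temp`, `timestamp`,
#'   or pre-projected `u`, `v`) to the file's column names.
#' @param ref_lat,ref_lon Reference point of the local equirectangular
#'   projection; defaults to the centroid of the input coordinates.
#' @param delim CSV delimiter.
#' @return An [observation_set()].
#' @export
read_observations <- function(path,
                              network_kind = c("low_cost", "regulatory"),
                              format = c("csv", "json"),
                              column_map = c(id = "id", lon = "lon",
                                             lat = "lat", pm25 = "pm25"),
                              ref_lat = NULL, ref_lon = NULL,
                              delim = ",") {
  network_kind <- match.arg(network_kind)
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort_pm(paste0("input file does not exist: ", path), "io_error")
  }
  raw <- switch(format,
    csv = tryCatch(
      readr::read_delim(path, delim = delim, show_col_types = FALSE,
                        progress = FALSE),
      error = function(e) abort_pm(paste0("failed to read ", path, ": ",
                                          conditionMessage(e)), "io_error")
    ),
    json = {
      parsed <- tryCatch(jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
                         error = function(e) abort_pm(
                           paste0("failed to parse JSON: ",
                                  conditionMessage(e)), "io_error"))
      if (!is.data.frame(parsed)) {
        abort_pm("JSON input must be an array of flat objects.", "io_error")
      }
      tibble::as_tibble(parsed)
    }
  )
  if (nrow(raw) == 0) {
    abort_pm(paste0("input file is empty: ", path), "empty_input_error")
  }

  has_uv <- all(c("u", "v") %in% names(column_map))
  mandatory <- if (has_uv) c("id", "u", "v", "pm25") else c("id", "lon", "lat", "pm25")
  missing_map <- setdiff(mandatory, names(column_map))
  if (length(missing_map) > 0) {
    abort_pm(paste0("column_map must name: ", paste(missing_map, collapse = ", ")),
             "configuration_error")
  }
  missing_cols <- setdiff(unname(column_map[mandatory]), names(raw))
  if (length(missing_cols) > 0) {
    abort_pm(paste0("mapped column(s) absent from file: ",
                    paste(missing_cols, collapse = ", ")),
             "configuration_error")
  }

  present <- column_map[unname(column_map) %in% names(raw)]
  out <- raw[, unname(present), drop = FALSE]
  names(out) <- names(present)

  if (has_uv) {
    crs_note <- "pre-projected planar coordinates supplied by caller (meters)"
  } else {
    lon <- as.numeric(out$lon)
    lat <- as.numeric(out$lat)
    if (is.null(ref_lat)) ref_lat <- mean(lat, na.rm = TRUE)
    if (is.null(ref_lon)) ref_lon <- mean(lon, na.rm = TRUE)
    uv <- project_lonlat(lon, lat, ref_lat = ref_lat, ref_lon = ref_lon,
                         origin_at_ref = TRUE)
    out$u <- uv$u
    out$v <- uv$v
    out$lon <- NULL
    out$lat <- NULL
    crs_note <- sprintf(
      "local equirectangular projection, ref_lat=%.5f deg, ref_lon=%.5f deg, R=%d m",
      ref_lat, ref_lon, EARTH_RADIUS_M)
  }
  observation_set(out, network_kind = network_kind, crs_note = crs_note)
}

#' Project geographic coordinates to local planar meters
#'
#' Local equirectangular projection: `u = R cos(ref_lat) (lon - ref_lon)`
#' and `v = R lat` (angles in radians, `R` = 6,371,000 m). Over a regional
#' study extent (a few hundred km at low latitude) its distance distortion
#' relative to great-circle distance is well below 1%. Deterministic and
#' invertible over such extents.
#'
#' @param lon,lat Coordinates in decimal degrees (vectorized).
#' @param ref_lat Reference latitude (degrees) fixing the cosine scale.
#' @param ref_lon Reference longitude (degrees); `u` is measured from it.
#' @param origin_at_ref If `TRUE`, shift the origin so the reference point
#'   maps to `(0, 0)` (i.e. subtract `R * ref_lat` from `v`).
#' @return A tibble with columns `u`, `v` in meters.
#' @examples
#' project_lonlat(121, 23.5, ref_lat = 23.5, ref_lon = 121,
#'                origin_at_ref = TRUE) # (0, 0)
#' @export
project_lonlat <- function(lon, lat, ref_lat, ref_lon = 0,
                           origin_at_ref = FALSE) {
  if (!all(is.finite(lon)) || !all(is.finite(lat)) ||
      !is.finite(ref_lat) || !is.finite(ref_lon)) {
    abort_pm("coordinates must be finite.", "value_error")
  }
  if (any(abs(lat) >= 90)) {
    abort_pm("|lat| must be < 90 degrees.", "value_error")
  }
  deg2rad <- pi / 180
  u <- EARTH_RADIUS_M * cos(ref_lat * deg2rad) * (lon - ref_lon) * deg2rad
  v <- EARTH_RADIUS_M * lat * deg2rad
  if (origin_at_ref) {
    v <- v - EARTH_RADIUS_M * ref_lat * deg2rad
  }
  tibble::tibble(u = u, v = v)
}

#' Write an observation set to CSV
#'
#' The written file round-trips losslessly through [read_observations()]
#' with `column_map` naming `u`/`v` (coordinates are stored as projected
#' meters, to full double precision).
#'
#' @param obs An [observation_set()]; must be non-empty.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(obs, path) {
  if (!inherits(obs, "obs_set") || nrow(obs) == 0) {
    abort_pm("`obs` must be a non-empty observation set.", "empty_input_error")
  }
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    abort_pm(paste0("directory does not exist: ", dir), "io_error")
  }
  readr::write_csv(tibble::as_tibble(obs), path, progress = FALSE)
  invisible(path)
}

#' @export
print.obs_set <- function(x, ...) {
  cat(sprintf("<obs_set: %s network, %d records, %d dropped at read>\n",
              attr(x, "network_kind"), nrow(x), attr(x, "n_dropped") %||% 0L))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
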