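#' Define a regular grid covering a point network
#'
#' Cell centers start at the padded bounding box's lower-left corner and are
#' spaced `resolution` meters apart; counts are `ceil(extent/resolution) + 1`
#' so the far edge is always covered.
#'
#' @param points Non-empty table with `u`, `v` (meters).
#' @param resolution Cell size in meters (> 0); default 2000 (a 2 km map).
#' @param padding Bounding-box expansion in meters on every side.
#' @return An object of class `grid_spec`: `origin` (`u0`, `v0`, lower-left
#'   cell center), `resolution`, `nx`, `ny`.
#' @export
make_grid <- function(points, resolution = 2000, padding = 0) {
  if (nrow(points) == 0) {
    abort_pm("`points` is empty.", "empty_input_error")
  }
  check_number(resolution, "resolution", positive = TRUE)
  check_number(padding, "padding")
  if (padding < 0) abort_pm("`padding` must be >= 0.", "value_error")
  u0 <- min(points$u) - padding
  v0 <- min(points$v) - padding
  nx <- as.integer(ceiling((max(points$u) + padding - u0) / resolution)) + 1L
  ny <- as.integer(ceiling((max(points$v) + padding - v0) / resolution)) + 1L
  structure(
    list(origin = c(u0 = u0, v0 = v0), resolution = resolution,
         nx = nx, ny = ny),
    class = "grid_spec"
  )
}

grid_centers <- function(spec) {
  list(u = spec$origin[["u0"]] + spec$resolution * (seq_len(spec$nx) - 1),
       v = spec$origin[["v0"]] + spec$resolution * (seq_len(spec$ny) - 1))
}

# distance below which a grid cell takes a data point's value exactly
IDW_COINCIDENT_M <- 1e-9

#' Inverse distance weighted interpolation onto a grid
#'
#' Each cell value is `sum(w_j z_j) / sum(w_j)` with `w_j = d_j^-power` over
#' all input points (global neighbourhood); the default power 2 gives
#' inverse-distance-squared weighting. A cell whose center lies within
#' 1e-9 m of a data point takes that point's value exactly. If `max_radius`
#' is set, cells with no point within it are masked (`NA`).
#'
#' @param points Non-empty [observation_set()] (or table with `u`, `v`,
#'   `pm25`).
#' @param spec A [make_grid()] specification.
#' @param power IDW power (> 0); default 2.
#' @param max_radius Optional masking radius in meters.
#' @return An object of class `grid_field`: `spec`, `values` (`ny` x `nx`
#'   matrix, rows indexed south to north), `mask` (logical matrix, `TRUE`
#'   where no estimate).
#' @export
idw_interpolate <- function(points, spec, power = 2, max_radius = NULL) {
  stopifnot(inherits(spec, "grid_spec"))
  if (nrow(points) == 0) {
    abort_pm("`points` is empty.", "empty_input_error")
  }
  check_number(power, "power", positive = TRUE)
  ctr <- grid_centers(spec)
  pu <- points$u
  pv <- points$v
  z <- points$pm25
  values <- matrix(NA_real_, nrow = spec$ny, ncol = spec$nx)
  # row-chunked dense distance computation keeps memory bounded
  for (iy in seq_len(spec$ny)) {
    du <- outer(ctr$u, pu, "-")               # nx x np
    dv <- ctr$v[iy] - pv
    d <- sqrt(du^2 + matrix(dv^2, nrow = spec$nx, ncol = length(pv),
                            byrow = TRUE))
    row_vals <- idw_rows(d, z, power, max_radius)
    values[iy, ] <- row_vals
  }
  structure(
    list(spec = spec, values = values, mask = is.na(values)),
    class = "grid_field"
  )
}

# IDW estimates for a (targets x points) distance matrix
idw_rows <- function(d, z, power, max_radius) {
  w <- d^(-power)
  if (!is.null(max_radius)) {
    w[d > max_radius] <- 0
  }
  est <- as.numeric((w %*% z) / rowSums(w))
  est[!is.finite(est)] <- NA_real_
  hit <- which(d < IDW_COINCIDENT_M, arr.ind = TRUE)
  if (nrow(hit) > 0) {
    # with several coincident points, the first listed wins
    first <- !duplicated(hit[, 1])
    est[hit[first, 1]] <- z[hit[first, 2]]
  }
  est
}

#' IDW prediction at arbitrary point locations (no grid)
#'
#' @param points Table with `u`, `v`, `pm25` (the data).
#' @param targets Table with `u`, `v` (where to predict).
#' @param power IDW power.
#' @param max_radius Optional masking radius in meters.
#' @return Numeric vector of estimates at the targets (`NA` where masked).
#' @export
idw_at <- function(points, targets, power = 2, max_radius = NULL) {
  if (nrow(points) == 0) abort_pm("`points` is empty.", "empty_input_error")
  check_number(power, "power", positive = TRUE)
  d <- sqrt(outer(targets$u, points$u, "-")^2 +
              outer(targets$v, points$v, "-")^2)
  idw_rows(d, points$pm25, power, max_radius)
}

#' Convert a grid field to a (u, v, value) tibble
#' @param x A `grid_field`.
#' @param ... Unused.
#' @return Tibble with one row per unmasked cell.
#' @method as_tibble grid_field
#' @export
as_tibble.grid_field <- function(x, ...) {
  ctr <- grid_centers(x$spec)
  tibble::tibble(
    u = rep(ctr$u, each = x$spec$ny),
    v = rep(ctr$v, times = x$spec$nx),
    value = as.numeric(x$values)
  )[!as.logical(x$mask), ]
}

#' @export
print.grid_field <- function(x, ...) {
  vals <- x$values[!as.logical(x$mask)]
  cat(sprintf(
    "<grid_field: %d x %d cells at %g m, %d masked>\n  value range %.2f - %.2f ug/m3\n",
    x$spec$ny, x$spec$nx, x$spec$resolution, sum(x$mask),
    min(vals), max(vals)))
  invisible(x)
}

#' Bilinear lookup of a grid field at point locations
#'
#' @param field A `grid_field`.
#' @param u,v Coordinates in meters (vectorized).
#' @return Interpolated values; `NA` outside the grid or where any of the
#'   four surrounding cells is masked.
#' @export
grid_lookup <- function(field, u, v) {
  spec <- field$spec
  fu <- (u - spec$origin[["u0"]]) / spec$resolution
  fv <- (v - spec$origin[["v0"]]) / spec$resolution
  ix <- floor(fu); iy <- floor(fv)
  # clamp exact top/right edge into the last cell
  ix[fu == spec$nx - 1] <- spec$nx - 2
  iy[fv == spec$ny - 1] <- spec$ny - 2
  out <- rep(NA_real_, length(u))
  ok <- ix >= 0 & ix <= spec$nx - 2 & iy >= 0 & iy <= spec$ny - 2
  if (spec$nx == 1 || spec$ny == 1) {
    # degenerate 1-cell axis: nearest value
    jx <- pmin(pmax(round(fu), 0), spec$nx - 1)
    jy <- pmin(pmax(round(fv), 0), spec$ny - 1)
    ok1 <- abs(fu - jx) <= 0.5 + 1e-9 & abs(fv - jy) <= 0.5 + 1e-9
    out[ok1] <- field$values[cbind(jy[ok1] + 1, jx[ok1] + 1)]
    return(out)
  }
  tx <- fu - ix; ty <- fv - iy
  i <- which(ok)
  v00 <- field$values[cbind(iy[i] + 1, ix[i] + 1)]
  v01 <- field$values[cbind(iy[i] + 1, ix[i] + 2)]
  v10 <- field$values[cbind(iy[i] + 2, ix[i] + 1)]
  v11 <- field$values[cbind(iy[i] + 2, ix[i] + 2)]
  out[i] <- (1 - ty[i]) * ((1 - tx[i]) * v00 + tx[i] * v01) +
    ty[i] * ((1 - tx[i]) * v10 + tx[i] * v11)
  out
}

#' Evaluate map accuracy at reference stations
#'
#' Compares each station's observed PM2.5 to the mapped estimate at its
#' coordinate, either by bilinear lookup of a gridded field
#' (`mode = "grid_lookup"`) or by re-running the IDW directly at the station
#' locations from the calibrated sensor points, with no grid
#' (`mode = "loo_idw"`). Stations falling in masked or out-of-grid areas are
#' excluded with a warning.
#'
#' @param field A `grid_field` (for `grid_lookup`) or a point table with
#'   `u`, `v`, `pm25` (for `loo_idw`).
#' @param stations Non-empty [observation_set()] of reference stations.
#' @param mode `"grid_lookup"` or `"loo_idw"`.
#' @param power IDW power for `loo_idw`.
#' @return An object of class `map_evaluation`: `rmse` (µg/m³), `n_used`,
#'   `per_station` (tibble `station_id`, `observed`, `estimated`, `error`).
#' @export
evaluate_map <- function(field, stations, mode = c("grid_lookup", "loo_idw"),
                         power = 2) {
  mode <- match.arg(mode)
  if (nrow(stations) == 0) {
    abort_pm("`stations` is empty.", "empty_input_error")
  }
  est <- switch(mode,
    grid_lookup = {
      stopifnot(inherits(field, "grid_field"))
      grid_lookup(field, stations$u, stations$v)
    },
    loo_idw = {
      if (inherits(field, "grid_field") || is.null(field$u)) {
        abort_pm(
          "`loo_idw` needs the calibrated point table (u, v, pm25), not a grid.",
          "value_error")
      }
      idw_at(field, stations, power = power)
    }
  )
  ok <- is.finite(est)
  if (any(!ok)) {
    warning(sprintf("%d station(s) outside the valid mapped area were excluded",
                    sum(!ok)))
  }
  err <- stations$pm25[ok] - est[ok]
  structure(
    list(
      rmse = sqrt(mean(err^2)),
      n_used = sum(ok),
      mode = mode,
      per_station = tibble::tibble(
        station_id = stations$id[ok],
        observed = stations$pm25[ok],
        estimated = est[ok],
        error = err
      )
    ),
    class = "map_evaluation"
  )
}

#' @export
print.map_evaluation <- function(x, ...) {
  cat(sprintf("<map_evaluation (%s): RMSE = %.3f ug/m3 over %d stations>\n",
              x$mode, x$rmse, x$n_used))
  invisible(x)
}

#' Write a grid field as ESRI ASCII grid and/or CSV
#'
#' The `.asc` header uses cell-corner convention (`xllcorner` = origin −
#' resolution/2) and `NODATA_value -9999` for masked cells; rows are written
#' north to south as the format requires. The CSV holds `(u, v, value)` cell
#' centers.
#'
#' @param field A `grid_field`.
#' @param path_asc,path_csv Output paths (either may be `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_grid <- function(field, path_asc = NULL, path_csv = NULL) {
  stopifnot(inherits(field, "grid_field"))
  if (!is.null(path_asc)) {
    spec <- field$spec
    vals <- field$values
    vals[is.na(vals)] <- -9999
    header <- c(
      sprintf("ncols %d", spec$nx),
      sprintf("nrows %d", spec$ny),
      sprintf("xllcorner %.6f", spec$origin[["u0"]] - spec$resolution / 2),
      sprintf("yllcorner %.6f", spec$origin[["v0"]] - spec$resolution / 2),
      sprintf("cellsize %.6f", spec$resolution),
      "NODATA_value -9999"
    )
    rows <- apply(vals[rev(seq_len(spec$ny)), , drop = FALSE], 1,
                  function(r) paste(sprintf("%.10g", r), collapse = " "))
    writeLines(c(header, rows), path_asc)
  }
  if (!is.null(path_csv)) {
    readr::write_csv(as_tibble.grid_field(field), path_csv, progress = FALSE)
  }
  invisible(c(path_asc, path_csv))
}
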