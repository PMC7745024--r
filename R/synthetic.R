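#' Specify a synthetic paired sensor/station scenario
#'
#' Defines a rectangular study domain with a closed-form ground-truth PM2.5
#' field (sum of Gaussian plumes over a background), a dense low-cost sensor
#' network whose readings are distorted by smooth multiplicative
#' (`gamma(u, v)`) and additive (`alpha(u, v)`) bias surfaces plus Gaussian
#' noise, and a sparse unbiased regulatory network. Because truth and bias
#' are closed-form, calibration recovery can be scored exactly.
#'
#' The bias surfaces are low-order trigonometric forms over the domain
#' (width `W`, height `H`):
#' \deqn{\gamma(u,v) = \gamma_{mid} + \gamma_{amp} \sin(\pi u/W)\cos(\pi v/H)}
#' \deqn{\alpha(u,v) = \alpha_{mid} + \alpha_{amp} \cos(\pi u/W)\sin(2\pi v/H)}
#' `bias_form = "linear"` replaces both by affine ramps in `u` (useful for
#' sharp parameter-recovery checks), and `"constant"` freezes them at their
#' mid values (spatially homogeneous bias).
#'
#' @param width,height Domain size in meters (easting x northing).
#' @param n_sensors,n_stations Network sizes; `n_stations >= 10`,
#'   `n_sensors >= n_stations`.
#' @param plumes Tibble with columns `cu`, `cv` (center, m), `amplitude`
#'   (µg/m³) and `length_scale` (m); amplitudes must be `>= 0` so the truth
#'   field stays nonnegative.
#' @param background Background concentration (µg/m³, `>= 0`).
#' @param gamma_mid,gamma_amp Multiplicative bias surface parameters.
#' @param alpha_mid,alpha_amp Additive bias surface parameters (µg/m³).
#' @param bias_form `"trig"`, `"linear"` or `"constant"`.
#' @param noise_sd_sensor,noise_sd_station Observation noise SDs (µg/m³).
#' @param collocation_radius Each station is guaranteed one sensor within
#'   this distance (m); 0 places it exactly at the station.
#' @param include_rh If `TRUE`, a smooth relative-humidity surface (%) is
#'   attached to the sensor records as covariate `rh`.
#' @param seed Integer seed; identical seed and parameters give identical
#'   networks.
#' @return An object of class `pm_scenario` (a named list of the above).
#' @export
pm_scenario <- function(width = 150e3, height = 400e3,
                        n_sensors = 2963, n_stations = 76,
                        plumes = default_plumes(),
                        background = 17,
                        gamma_mid = 1.45, gamma_amp = 0.35,
                        alpha_mid = 7.5, alpha_amp = 7.5,
                        bias_form = c("trig", "linear", "constant"),
                        noise_sd_sensor = 5, noise_sd_station = 1.5,
                        collocation_radius = 400,
                        include_rh = FALSE,
                        seed = 1L) {
  bias_form <- match.arg(bias_form)
  scen <- list(
    width = width, height = height,
    n_sensors = as.integer(n_sensors), n_stations = as.integer(n_stations),
    plumes = tibble::as_tibble(plumes),
    background = background,
    gamma_mid = gamma_mid, gamma_amp = gamma_amp,
    alpha_mid = alpha_mid, alpha_amp = alpha_amp,
    bias_form = bias_form,
    noise_sd_sensor = noise_sd_sensor,
    noise_sd_station = noise_sd_station,
    collocation_radius = collocation_radius,
    include_rh = isTRUE(include_rh),
    seed = as.integer(seed)
  )
  validate_scenario(scen)
  structure(scen, class = "pm_scenario")
}

default_plumes <- function() {
  tibble::tibble(
    cu = c(35e3, 45e3, 40e3),
    cv = c(110e3, 210e3, 320e3),
    amplitude = c(62, 50, 28),
    length_scale = c(45e3, 40e3, 35e3)
  )
}

validate_scenario <- function(scen) {
  if (scen$n_stations < 10) {
    abort_pm("scenario needs at least 10 stations.", "scenario_validation_error")
  }
  if (scen$n_sensors < scen$n_stations) {
    abort_pm("scenario needs n_sensors >= n_stations.", "scenario_validation_error")
  }
  if (scen$width <= 0 || scen$height <= 0) {
    abort_pm("domain dimensions must be positive.", "scenario_validation_error")
  }
  if (scen$background < 0 || any(scen$plumes$amplitude < 0) ||
      any(scen$plumes$length_scale <= 0)) {
    abort_pm("truth field parameters would allow negative concentrations.",
             "scenario_validation_error")
  }
  if (scen$noise_sd_sensor < 0 || scen$noise_sd_station < 0) {
    abort_pm("noise SDs must be >= 0.", "scenario_validation_error")
  }
  invisible(scen)
}

#' Default heterogeneous scenario
#'
#' A fully specified preset on a 150 km (easting) x 400 km (northing)
#' domain: three Gaussian plumes along the western side over a 17 µg/m³
#' background (hotspots in the central and southwestern areas), 2,963
#' low-cost sensors, 76 regulatory stations, smooth multiplicative bias over
#' `[1.1, 1.8]` and additive bias over `[0, 15]` µg/m³, sensor noise SD
#' 5 µg/m³ and station noise SD 1.5 µg/m³.
#'
#' @param seed Integer seed.
#' @param ... Overrides forwarded to [pm_scenario()].
#' @return A `pm_scenario`.
#' @export
default_scenario <- function(seed = 1L, ...) {
  pm_scenario(seed = seed, ...)
}

#' Evaluate the scenario's closed-form surfaces at coordinates
#'
#' @param scen A `pm_scenario`.
#' @param u,v Coordinates in meters (vectorized).
#' @return Tibble with `truth` (µg/m³), `gamma`, `alpha` (µg/m³), and `rh`
#'   (%) if the scenario includes humidity.
#' @export
scenario_fields <- function(scen, u, v) {
  stopifnot(inherits(scen, "pm_scenario"))
  truth <- rep(scen$background, length(u))
  for (k in seq_len(nrow(scen$plumes))) {
    d2 <- (u - scen$plumes$cu[k])^2 + (v - scen$plumes$cv[k])^2
    truth <- truth +
      scen$plumes$amplitude[k] * exp(-d2 / (2 * scen$plumes$length_scale[k]^2))
  }
  W <- scen$width; H <- scen$height
  shape_g <- switch(scen$bias_form,
    trig = sin(pi * u / W) * cos(pi * v / H),
    linear = u / W - 0.5,
    constant = rep(0, length(u))
  )
  shape_a <- switch(scen$bias_form,
    trig = cos(pi * u / W) * sin(2 * pi * v / H),
    linear = u / W - 0.5,
    constant = rep(0, length(u))
  )
  out <- tibble::tibble(
    truth = truth,
    gamma = scen$gamma_mid + scen$gamma_amp * shape_g,
    alpha = scen$alpha_mid + scen$alpha_amp * shape_a
  )
  if (scen$include_rh) {
    out$rh <- 82 + 8 * sin(2 * pi * v / H) * cos(pi * u / W)
  }
  out
}

#' Generate the paired synthetic networks
#'
#' Station readings are `truth + station noise` (reference grade); sensor
#' readings are `alpha(u, v) + gamma(u, v) * truth + sensor noise`. The
#' first `n_stations` sensors are placed uniformly within
#' `collocation_radius` of each station, guaranteeing a collocatable pair
#' everywhere; the rest are uniform over the domain. All randomness derives
#' from the scenario seed (the caller's RNG state is untouched).
#'
#' @param scen A [pm_scenario()].
#' @return A list of class `pm_network`: `sensors` and `stations`
#'   ([observation_set()]s), and `truth` — a tibble with `network`, `id`,
#'   `u`, `v`, `truth` for every site.
#' @export
generate_network <- function(scen) {
  stopifnot(inherits(scen, "pm_scenario"))
  validate_scenario(scen)
  withr::with_seed(scen$seed, {
    su <- stats::runif(scen$n_stations, 0, scen$width)
    sv <- stats::runif(scen$n_stations, 0, scen$height)

    n_free <- scen$n_sensors - scen$n_stations
    # one guaranteed sensor near each station, uniform in a disk
    r <- scen$collocation_radius * sqrt(stats::runif(scen$n_stations))
    th <- stats::runif(scen$n_stations, 0, 2 * pi)
    gu <- pmin(pmax(su + r * cos(th), 0), scen$width)
    gv <- pmin(pmax(sv + r * sin(th), 0), scen$height)
    fu <- stats::runif(n_free, 0, scen$width)
    fv <- stats::runif(n_free, 0, scen$height)
    lu <- c(gu, fu)
    lv <- c(gv, fv)

    st_fields <- scenario_fields(scen, su, sv)
    se_fields <- scenario_fields(scen, lu, lv)
    if (any(st_fields$truth < 0) || any(se_fields$truth < 0)) {
      abort_pm("scenario produced negative truth values.",
               "scenario_validation_error")
    }

    station_pm <- st_fields$truth +
      stats::rnorm(scen$n_stations, 0, scen$noise_sd_station)
    sensor_pm <- se_fields$alpha + se_fields$gamma * se_fields$truth +
      stats::rnorm(scen$n_sensors, 0, scen$noise_sd_sensor)

    width_id <- function(n) formatC(seq_len(n), width = nchar(n), flag = "0")
    stations_df <- tibble::tibble(
      id = paste0("st", width_id(scen$n_stations)),
      u = su, v = sv, pm25 = pmax(station_pm, 0)
    )
    sensors_df <- tibble::tibble(
      id = paste0("lc", width_id(scen$n_sensors)),
      u = lu, v = lv, pm25 = pmax(sensor_pm, 0)
    )
    if (scen$include_rh) {
      sensors_df$rh <- se_fields$rh
    }
    crs <- "synthetic planar domain (meters)"
    structure(
      list(
        sensors = observation_set(sensors_df, "low_cost", crs),
        stations = observation_set(stations_df, "regulatory", crs),
        truth = dplyr::bind_rows(
          tibble::tibble(network = "regulatory", id = stations_df$id,
                         u = su, v = sv, truth = st_fields$truth),
          tibble::tibble(network = "low_cost", id = sensors_df$id,
                         u = lu, v = lv, truth = se_fields$truth)
        ),
        scenario = scen
      ),
      class = "pm_network"
    )
  })
}

#' Sample directly from a varying-coefficient calibration model
#'
#' Draws anchors uniformly over a rectangular domain, covariate values
#' uniformly over `x_range`, and responses
#' `y = beta0(u) + beta1(u) x + noise` with both coefficient surfaces affine
#' ramps in the easting: `beta(u) = base + ramp * u / width`. Because the
#' generating surfaces are known exactly, kernel-weighted coefficient
#' recovery can be scored sharply (a collocated training set with zero pair
#' separation is returned, plus the true surfaces at the anchors).
#'
#' @param n Number of anchors.
#' @param beta0,beta1 Length-2 numeric `c(base, ramp)` for the intercept
#'   (µg/m³) and slope surfaces.
#' @param width,height Domain size in meters.
#' @param x_range Range of the covariate draws (µg/m³).
#' @param noise_sd Response noise SD (µg/m³); 0 gives exact data.
#' @param seed Integer seed.
#' @return A list: `pairs` (a `collocated_pairs` training set) and `truth`
#'   (tibble `u`, `v`, `beta0`, `beta1` of the generating surfaces at the
#'   anchors).
#' @export
generate_vc_data <- function(n, beta0 = c(5, 10), beta1 = c(0.6, 0.4),
                             width = 150e3, height = 400e3,
                             x_range = c(20, 100), noise_sd = 0, seed = 1L) {
  stopifnot(length(beta0) == 2, length(beta1) == 2, n >= 5)
  withr::with_seed(as.integer(seed), {
    u <- stats::runif(n, 0, width)
    v <- stats::runif(n, 0, height)
    x <- stats::runif(n, x_range[1], x_range[2])
    b0 <- beta0[1] + beta0[2] * u / width
    b1 <- beta1[1] + beta1[2] * u / width
    y <- b0 + b1 * x + stats::rnorm(n, 0, noise_sd)
    ids <- formatC(seq_len(n), width = nchar(n), flag = "0")
    pairs <- new_collocated_pairs(
      tibble::tibble(station_id = paste0("st", ids),
                     sensor_id = paste0("lc", ids),
                     distance = 0, y = y, x1 = x, u = u, v = v),
      max_distance = Inf, n_excluded = 0L, B = 1L, covariates = "pm25")
    list(pairs = pairs,
         truth = tibble::tibble(u = u, v = v, beta0 = b0, beta1 = b1))
  })
}

#' @export
print.pm_scenario <- function(x, ...) {
  cat(sprintf("<pm_scenario: %.0f x %.0f km, %d sensors, %d stations, bias '%s', seed %d>\n",
              x$width / 1000, x$height / 1000, x$n_sensors, x$n_stations,
              x$bias_form, x$seed))
  invisible(x)
}

#' @export
print.pm_network <- function(x, ...) {
  cat(sprintf("<pm_network: %d sensors (mean %.1f ug/m3), %d stations (mean %.1f ug/m3)>\n",
              nrow(x$sensors), mean(x$sensors$pm25),
              nrow(x$stations), mean(x$stations$pm25)))
  invisible(x)
}

#' Read/write a scenario as a JSON config
#'
#' @param scen A `pm_scenario`.
#' @param path JSON path.
#' @return `write_scenario`: `path` invisibly; `read_scenario`: a
#'   `pm_scenario`.
#' @export
write_scenario <- function(scen, path) {
  stopifnot(inherits(scen, "pm_scenario"))
  jsonlite::write_json(unclass(scen), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  raw <- jsonlite::fromJSON(path)
  scenario_from_list(raw)
}

scenario_from_list <- function(raw) {
  args <- raw[intersect(names(raw), names(formals(pm_scenario)))]
  if (!is.null(args$plumes)) args$plumes <- tibble::as_tibble(args$plumes)
  do.call(pm_scenario, args)
}
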