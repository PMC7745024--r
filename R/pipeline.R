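#' Default run configuration
#'
#' Nested list of pipeline settings. Defaults: collocation cut-off 2000 m,
#' IDW power 2, map resolution 2000 m, bandwidth `"auto"`
#' (leave-one-out cross-validation).
#'
#' @param ... Overrides as `section.key = value` dotted names (e.g.
#'   `collocation.max_distance_m = 3000`) or whole sections as lists.
#' @return A nested configuration list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    paths = list(sensor_input = NULL, station_input = NULL,
                 output_dir = "pmcalibrate_out"),
    collocation = list(max_distance_m = 2000),
    calibration = list(bandwidth_m = "auto", bandwidth_candidates = NULL,
                       covariates = list(), ridge_epsilon = 1e-8),
    mapping = list(resolution_m = 2000, power = 2, padding_m = 0),
    synthetic = NULL,
    seed = 1L,
    log_level = "info"
  )
  cfg <- apply_overrides(cfg, list(...))
  structure(cfg, class = c("run_config", "list"))
}

apply_overrides <- function(cfg, overrides) {
  for (nm in names(overrides)) {
    path <- strsplit(nm, ".", fixed = TRUE)[[1]]
    cfg <- set_in(cfg, path, overrides[[nm]])
  }
  cfg
}

set_in <- function(x, path, value) {
  if (length(path) == 1) {
    x[[path]] <- value
    return(x)
  }
  if (is.null(x[[path[1]]])) x[[path[1]]] <- list()
  x[[path[1]]] <- set_in(x[[path[1]]], path[-1], value)
  x
}

#' Read a run configuration from YAML or JSON
#'
#' Unknown keys raise a configuration error naming the offending key path;
#' omitted keys take their [default_config()] values.
#'
#' @param path Config file (`.yaml`/`.yml` or `.json`).
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    abort_pm(paste0("config file not found: ", path), "io_error")
  }
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  }
  cfg <- unclass(default_config())
  check_keys <- function(ref, got, prefix = "") {
    for (nm in names(got)) {
      if (!nm %in% names(ref)) {
        abort_pm(paste0("unknown config key: ", prefix, nm),
                 "configuration_error")
      }
    }
  }
  check_keys(cfg, raw)
  for (sec in names(raw)) {
    if (is.list(cfg[[sec]]) && is.list(raw[[sec]]) && sec != "synthetic") {
      check_keys(cfg[[sec]], raw[[sec]], paste0(sec, "."))
      for (k in names(raw[[sec]])) cfg[[sec]][[k]] <- raw[[sec]][[k]]
    } else {
      cfg[[sec]] <- raw[[sec]]
    }
  }
  structure(cfg, class = c("run_config", "list"))
}

out_path <- function(config, ...) {
  dir <- config$paths$output_dir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  file.path(dir, ...)
}

#' Pipeline stages
#'
#' Config-driven stages mirroring the analysis flow: simulate (synthetic
#' networks), collocate, calibrate (always both the global and the spatial
#' model), map, or all of them in order. Each stage writes its artifacts
#' into `paths$output_dir` and a machine-readable `manifest.json` (config
#' echo, input hashes, per-stage counts, selected bandwidth, package
#' version). Runs with identical config and seed produce identical numeric
#' outputs.
#'
#' @param config A [default_config()] / [read_config()] list.
#' @return `run_simulate`: a `pm_network`; `run_collocate`:
#'   `collocated_pairs`; `run_calibrate`: list with both models and their
#'   residual reports; `run_map`: list of grid fields and map evaluations;
#'   `run_all`: list with all of the above. All invisibly write files.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
run_simulate <- function(config = default_config()) {
  scen_spec <- config$synthetic
  if (is.null(scen_spec)) {
    scen <- default_scenario(seed = config$seed)
  } else {
    scen_spec$seed <- scen_spec$seed %||% config$seed
    scen <- scenario_from_list(scen_spec)
  }
  net <- generate_network(scen)
  write_observations(net$sensors, out_path(config, "sensors.csv"))
  write_observations(net$stations, out_path(config, "stations.csv"))
  readr::write_csv(net$truth, out_path(config, "truth.csv"), progress = FALSE)
  pm_log(sprintf("simulated %d sensors / %d stations (seed %d)",
                 nrow(net$sensors), nrow(net$stations), scen$seed))
  invisible(net)
}

load_networks <- function(config) {
  uv_map <- c(id = "id", u = "u", v = "v", pm25 = "pm25", rh = "rh",
              temp = "temp", timestamp = "timestamp")
  sensor_path <- config$paths$sensor_input %||% out_path(config, "sensors.csv")
  station_path <- config$paths$station_input %||% out_path(config, "stations.csv")
  list(
    sensors = read_observations(sensor_path, "low_cost", "csv", uv_map),
    stations = read_observations(station_path, "regulatory", "csv", uv_map)
  )
}

#' @rdname pipeline
#' @export
run_collocate <- function(config = default_config()) {
  nets <- load_networks(config)
  covs <- as.character(unlist(config$calibration$covariates))
  pairs <- collocate_nearest(nets$stations, nets$sensors, covariates = covs)
  d_before <- mean_pair_distance(pairs)
  pairs <- filter_pairs(pairs, config$collocation$max_distance_m)
  pm_log(sprintf(
    "collocated %d pairs (%d excluded > %g m); mean distance %.0f -> %.0f m",
    nrow(pairs), attr(pairs, "n_excluded"), config$collocation$max_distance_m,
    d_before, mean_pair_distance(pairs)))
  write_pairs(pairs, out_path(config, "pairs.csv"))
  invisible(pairs)
}

#' @rdname pipeline
#' @export
run_calibrate <- function(config = default_config()) {
  nets <- load_networks(config)
  pairs <- run_collocate(config)

  global <- fit_global(pairs)
  bw <- config$calibration$bandwidth_m
  cands <- config$calibration$bandwidth_candidates
  if (!is.null(cands)) cands <- as.numeric(unlist(cands))
  spatial <- fit_spatial(pairs, bandwidth = if (identical(bw, "auto")) "auto" else as.numeric(bw),
                         ridge_epsilon = config$calibration$ridge_epsilon,
                         candidates = cands)

  rep_global <- residual_report(pairs, global$fitted)
  rep_spatial <- residual_report(pairs, spatial$fitted)
  cv_global <- cv_rmse(pairs, "global")
  cv_spatial <- cv_rmse(pairs, "spatial", bandwidth = spatial$bandwidth,
                        ridge_epsilon = config$calibration$ridge_epsilon)

  write_model(global, out_path(config, "model_global.json"),
              provenance = list(seed = config$seed))
  write_model(spatial, out_path(config, "model_spatial.json"),
              provenance = list(seed = config$seed))
  write_residual_report(rep_global,
                        out_path(config, "residuals_global.csv"),
                        out_path(config, "report_global.json"))
  write_residual_report(rep_spatial,
                        out_path(config, "residuals_spatial.csv"),
                        out_path(config, "report_spatial.json"))
  jsonlite::write_json(
    list(global = list(r_squared = rep_global$r_squared,
                       rmse = rep_global$rmse, loo_cv_rmse = cv_global),
         spatial = list(r_squared = rep_spatial$r_squared,
                        rmse = rep_spatial$rmse, loo_cv_rmse = cv_spatial,
                        bandwidth = spatial$bandwidth)),
    out_path(config, "calibration_comparison.json"),
    auto_unbox = TRUE, digits = NA)
  pm_log(sprintf(
    "calibration: global R^2 %.3f / RMSE %.2f; spatial R^2 %.3f / RMSE %.2f (bandwidth %.0f m)",
    rep_global$r_squared, rep_global$rmse, rep_spatial$r_squared,
    rep_spatial$rmse, spatial$bandwidth))
  invisible(list(pairs = pairs, global = global, spatial = spatial,
                 report_global = rep_global, report_spatial = rep_spatial,
                 cv_global = cv_global, cv_spatial = cv_spatial))
}

#' @rdname pipeline
#' @param calibration Optional result of [run_calibrate()] to reuse.
#' @export
run_map <- function(config = default_config(), calibration = NULL) {
  nets <- load_networks(config)
  if (is.null(calibration)) calibration <- run_calibrate(config)
  sensors <- nets$sensors

  cal_global <- calibrate(calibration$global, sensors)
  cal_spatial <- calibrate(calibration$spatial, sensors)

  spec <- make_grid(sensors, resolution = config$mapping$resolution_m,
                    padding = config$mapping$padding_m)
  grid_global <- idw_interpolate(cal_global, spec, power = config$mapping$power)
  grid_spatial <- idw_interpolate(cal_spatial, spec, power = config$mapping$power)

  eval_global <- evaluate_map(cal_global, nets$stations, "loo_idw",
                              power = config$mapping$power)
  eval_spatial <- evaluate_map(cal_spatial, nets$stations, "loo_idw",
                               power = config$mapping$power)
  eval_global_grid <- evaluate_map(grid_global, nets$stations, "grid_lookup")
  eval_spatial_grid <- evaluate_map(grid_spatial, nets$stations, "grid_lookup")

  write_grid(grid_global, out_path(config, "map_global.asc"),
             out_path(config, "map_global.csv"))
  write_grid(grid_spatial, out_path(config, "map_spatial.asc"),
             out_path(config, "map_spatial.csv"))
  jsonlite::write_json(
    list(
      global = list(rmse_idw = eval_global$rmse,
                    rmse_grid = eval_global_grid$rmse),
      spatial = list(rmse_idw = eval_spatial$rmse,
                     rmse_grid = eval_spatial_grid$rmse),
      rmse_ratio_idw = eval_spatial$rmse / eval_global$rmse,
      rmse_reduction_pct_idw = 100 * (1 - eval_spatial$rmse / eval_global$rmse)
    ),
    out_path(config, "map_evaluation.json"), auto_unbox = TRUE, digits = NA)
  pm_log(sprintf("mapping RMSE at stations: global %.2f, spatial %.2f ug/m3",
                 eval_global$rmse, eval_spatial$rmse))
  invisible(list(grid_global = grid_global, grid_spatial = grid_spatial,
                 eval_global = eval_global, eval_spatial = eval_spatial,
                 eval_global_grid = eval_global_grid,
                 eval_spatial_grid = eval_spatial_grid,
                 calibrated_global = cal_global,
                 calibrated_spatial = cal_spatial))
}

#' @rdname pipeline
#' @export
run_all <- function(config = default_config()) {
  old <- options(pmcalibrate.log_level = config$log_level %||% "info")
  on.exit(options(old))
  net <- NULL
  if (is.null(config$paths$sensor_input)) {
    net <- run_simulate(config)
  }
  calibration <- run_calibrate(config)
  maps <- run_map(config, calibration = calibration)
  manifest <- list(
    package = "pmcalibrate",
    version = as.character(utils::packageVersion("pmcalibrate")),
    seed = config$seed,
    config = strip_null(unclass(config)),
    inputs = input_hashes(config),
    n_pairs = nrow(calibration$pairs),
    n_excluded = attr(calibration$pairs, "n_excluded"),
    selected_bandwidth_m = calibration$spatial$bandwidth,
    n_ridge_events = calibration$spatial$n_ridge,
    n_floored_global = attr(maps$calibrated_global, "n_floored"),
    n_floored_spatial = attr(maps$calibrated_spatial, "n_floored")
  )
  jsonlite::write_json(manifest, out_path(config, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(network = net, calibration = calibration, maps = maps,
                 manifest = manifest))
}

strip_null <- function(x) {
  if (!is.list(x)) return(x)
  x <- x[!vapply(x, is.null, logical(1))]
  lapply(x, strip_null)
}

input_hashes <- function(config) {
  files <- c(sensors = config$paths$sensor_input %||% out_path(config, "sensors.csv"),
             stations = config$paths$station_input %||% out_path(config, "stations.csv"))
  files <- files[file.exists(files)]
  as.list(tools::md5sum(files))
}
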