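test_that("grid dimensions follow the ceil-plus-one convention", {
  single <- make_obs("a", 1000, 2000, 10)
  spec1 <- make_grid(single, resolution = 2000, padding = 0)
  expect_equal(spec1$nx, 1L)
  expect_equal(spec1$ny, 1L)
  expect_equal(unname(spec1$origin), c(1000, 2000))

  pts <- make_obs(c("a", "b"), c(0, 10000), c(0, 4000), c(1, 2))
  spec2 <- make_grid(pts, resolution = 2000, padding = 0)
  expect_equal(spec2$nx, 6L)
  expect_equal(spec2$ny, 3L)

  expect_error(make_grid(pts, resolution = -2000), class = "value_error")
  expect_error(make_grid(pts, resolution = 0), class = "value_error")
})

test_that("IDW is exact at data points and symmetric between two points", {
  pts <- make_obs(c("a", "b"), c(0, 4000), c(0, 0), c(10, 20))
  spec <- make_grid(pts, resolution = 2000)
  field <- idw_interpolate(pts, spec, power = 2)
  # cells at the data points take the data values bit-for-bit
  expect_identical(field$values[1, 1], 10)
  expect_identical(field$values[1, 3], 20)
  # midpoint equidistant from 10 and 20 -> 15
  expect_equal(field$values[1, 2], 15)
})

test_that("IDW reproduces the hand-computed three-point value", {
  # target at distances 1000 m and 2000 m from values 30 and 60
  pts <- make_obs(c("a", "b"), c(1000, -2000), c(0, 0), c(30, 60))
  est <- idw_at(pts, tibble::tibble(u = 0, v = 0), power = 2)
  expect_equal(est, (30 / 1000^2 + 60 / 2000^2) / (1 / 1000^2 + 1 / 2000^2))
  expect_equal(est, 36)
})

test_that("IDW estimates are convex combinations of the inputs", {
  withr::with_seed(23, {
    pts <- make_obs(paste0("s", 1:40), runif(40, 0, 5e4), runif(40, 0, 5e4),
                    runif(40, 5, 95))
  })
  spec <- make_grid(pts, resolution = 2500, padding = 2000)
  field <- idw_interpolate(pts, spec)
  vals <- field$values[!field$mask]
  expect_gte(min(vals), min(pts$pm25))
  expect_lte(max(vals), max(pts$pm25))
})

test_that("IDW is translation invariant and linear in the values", {
  withr::with_seed(24, {
    df <- tibble::tibble(id = paste0("s", 1:15), u = runif(15, 0, 1e4),
                         v = runif(15, 0, 1e4), pm25 = runif(15, 10, 50))
  })
  pts <- observation_set(df, "low_cost")
  targets <- tibble::tibble(u = c(1234, 5678), v = c(4321, 8765))
  base <- idw_at(pts, targets)

  shifted <- observation_set(
    dplyr::mutate(df, u = u + 7e5, v = v - 3e5), "low_cost")
  targets2 <- dplyr::mutate(targets, u = u + 7e5, v = v - 3e5)
  expect_equal(idw_at(shifted, targets2), base, tolerance = 1e-9)

  scaled <- observation_set(dplyr::mutate(df, pm25 = 3.5 * pm25), "low_cost")
  expect_equal(idw_at(scaled, targets), 3.5 * base, tolerance = 1e-12)
})

test_that("masking leaves remote cells without an estimate", {
  pts <- make_obs(c("a", "b"), c(0, 20000), c(0, 0), c(10, 20))
  spec <- make_grid(pts, resolution = 2000)
  field <- idw_interpolate(pts, spec, max_radius = 3000)
  expect_true(any(field$mask))
  expect_false(field$mask[1, 1])
  ctr_idx <- 6  # cell at u = 10 km, 10 km from either point
  expect_true(field$mask[1, ctr_idx])
})

test_that("map evaluation is zero for an exactly matching field and follows hand arithmetic", {
  pts <- make_obs(paste0("s", 1:4), c(0, 2000, 0, 2000), c(0, 0, 2000, 2000),
                  c(10, 20, 30, 40))
  spec <- make_grid(pts, resolution = 2000)
  field <- idw_interpolate(pts, spec)
  stations <- make_obs(paste0("st", 1:4), pts$u, pts$v, pts$pm25,
                       kind = "regulatory")
  ev <- evaluate_map(field, stations, "grid_lookup")
  expect_equal(ev$rmse, 0, tolerance = 1e-12)
  expect_equal(ev$n_used, 4)

  # two stations with errors {3, 4} -> rmse = sqrt(12.5)
  stations2 <- make_obs(c("st1", "st2"), c(0, 2000), c(0, 0), c(13, 24),
                        kind = "regulatory")
  ev2 <- evaluate_map(field, stations2, "grid_lookup")
  expect_equal(sort(abs(ev2$per_station$error)), c(3, 4))
  expect_equal(ev2$rmse, sqrt(12.5), tolerance = 1e-12)
  expect_equal(ev2$rmse, 3.5355, tolerance = 1e-4)
})

test_that("stations outside the grid are excluded with a warning", {
  pts <- make_obs(c("a", "b"), c(0, 2000), c(0, 2000), c(10, 20))
  spec <- make_grid(pts, resolution = 2000)
  field <- idw_interpolate(pts, spec)
  stations <- make_obs(c("in", "out"), c(1000, 9e5), c(1000, 9e5), c(15, 15),
                       kind = "regulatory")
  expect_warning(ev <- evaluate_map(field, stations, "grid_lookup"),
                 "excluded")
  expect_equal(ev$n_used, 1)
})

test_that("grid lookup error shrinks as the grid is refined on a smooth field", {
  scen <- default_scenario(seed = 16, n_sensors = 1200, n_stations = 30,
                           gamma_amp = 0, gamma_mid = 1, alpha_mid = 0,
                           alpha_amp = 0, noise_sd_sensor = 0,
                           noise_sd_station = 0)
  net <- generate_network(scen)
  # noiseless unbiased sensors sample the truth field directly
  coarse <- evaluate_map(
    idw_interpolate(net$sensors, make_grid(net$sensors, resolution = 16000)),
    net$stations, "grid_lookup")
  fine <- evaluate_map(
    idw_interpolate(net$sensors, make_grid(net$sensors, resolution = 2000)),
    net$stations, "grid_lookup")
  expect_lt(fine$rmse, coarse$rmse)
  expect_lt(fine$rmse, 3)
})

test_that("the ESRI ASCII export carries the right header and round-trips values", {
  pts <- make_obs(paste0("s", 1:6), c(0, 2000, 4000, 0, 2000, 4000),
                  c(0, 0, 0, 2000, 2000, 2000), c(10, 20, 30, 40, 50, 60))
  spec <- make_grid(pts, resolution = 2000)
  field <- idw_interpolate(pts, spec)
  asc <- withr::local_tempfile(fileext = ".asc")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_grid(field, asc, csv)
  lines <- readLines(asc)
  expect_equal(lines[1], "ncols 3")
  expect_equal(lines[2], "nrows 2")
  expect_match(lines[3], "^xllcorner -1000")
  expect_match(lines[6], "NODATA_value -9999")
  # first data row is the northernmost: 40 50 60
  row1 <- as.numeric(strsplit(lines[7], " ")[[1]])
  expect_equal(row1, c(40, 50, 60))
  back <- readr::read_csv(csv, show_col_types = FALSE)
  expect_equal(nrow(back), 6)
  expect_setequal(back$value, pts$pm25)
})
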