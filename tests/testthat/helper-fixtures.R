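# Shared fixtures and independent oracles. Oracles deliberately use a
# different numerical route than the implementation (dense uncentered
# normal equations, exhaustive scans, two-pass sums).

make_obs <- function(ids, u, v, pm25, kind = "low_cost", ...) {
  observation_set(
    tibble::tibble(id = ids, u = u, v = v, pm25 = pm25, ...),
    network_kind = kind
  )
}

make_pairs <- function(y, x1, u, v, distance = 0, ...) {
  n <- length(y)
  extra <- list(...)
  df <- tibble::tibble(
    station_id = paste0("st", seq_len(n)),
    sensor_id = paste0("lc", seq_len(n)),
    distance = rep_len(distance, n),
    y = y, x1 = x1
  )
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  df$u <- u
  df$v <- v
  B <- 1L + length(extra)
  pmcalibrate:::new_collocated_pairs(
    df[, c("station_id", "sensor_id", "distance", "y",
           paste0("x", seq_len(B)), "u", "v")],
    max_distance = Inf, n_excluded = 0L, B = B,
    covariates = c("pm25", names(extra)))
}

# dense uncentered weighted normal equations: (X'WX)^-1 X'WY
oracle_wls <- function(X, w, y) {
  XtW <- t(X * w)
  solve(XtW %*% X, XtW %*% y)[, 1]
}

oracle_ols <- function(X, y) oracle_wls(X, rep(1, nrow(X)), y)

# exhaustive O(n*m) nearest-neighbour scan
oracle_nearest <- function(stations, sensors) {
  t(sapply(seq_len(nrow(stations)), function(i) {
    d <- sqrt((sensors$u - stations$u[i])^2 + (sensors$v - stations$v[i])^2)
    j <- which(d == min(d))
    j <- j[order(sensors$id[j])][1]
    c(j = j, d = d[j])
  }))
}

# great-circle distance (haversine), meters
haversine_m <- function(lon1, lat1, lon2, lat2) {
  r <- pi / 180
  dlat <- (lat2 - lat1) * r
  dlon <- (lon2 - lon1) * r
  a <- sin(dlat / 2)^2 + cos(lat1 * r) * cos(lat2 * r) * sin(dlon / 2)^2
  2 * 6371000 * asin(sqrt(a))
}

# random well-conditioned calibration instance for oracle-equivalence tests
random_instance <- function(seed, n = NULL, B = NULL) {
  withr::with_seed(seed, {
    if (is.null(n)) n <- sample(5:50, 1)
    if (is.null(B)) B <- sample(1:2, 1)
    u <- runif(n, 0, 100e3)
    v <- runif(n, 0, 100e3)
    x1 <- runif(n, 10, 120)
    y <- 4 + 0.7 * x1 + rnorm(n, 0, 5)
    if (B == 2) {
      x2 <- runif(n, 40, 95)
      y <- y + 0.15 * x2
      pairs <- make_pairs(y, x1, u, v, x2 = x2)
    } else {
      pairs <- make_pairs(y, x1, u, v)
    }
    pairs
  })
}

# a 76-station layout in which exactly 7 pairs exceed the 2 km cut-off;
# stations sit on a coarse grid (>= 18 km spacing) and each station's sole
# nearby sensor is offset by < 8 km, so every station pairs with "its own"
# sensor and the far/near split is guaranteed by construction
fixture_76_stations <- function(seed = 202) {
  withr::with_seed(seed, {
    n_st <- 76
    grid <- expand.grid(u = seq(10e3, 140e3, length.out = 8),
                        v = seq(20e3, 380e3, length.out = 10))[1:n_st, ]
    su <- grid$u
    sv <- grid$v
    far <- 1:7                  # these stations get only a distant sensor
    near <- 8:n_st
    th <- runif(n_st, 0, 2 * pi)
    off <- numeric(n_st)
    off[near] <- runif(length(near), 100, 1500)
    off[far] <- runif(7, 2500, 8000)
    lu <- su + off * cos(th)
    lv <- sv + off * sin(th)
    stations <- make_obs(paste0("st", sprintf("%02d", 1:n_st)), su, sv,
                         runif(n_st, 10, 80), kind = "regulatory")
    sensors <- make_obs(paste0("lc", sprintf("%02d", 1:n_st)), lu, lv,
                        runif(n_st, 10, 120))
    list(stations = stations, sensors = sensors)
  })
}
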