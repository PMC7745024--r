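#' Gaussian distance-decay kernel weight
#'
#' `w = exp(-d^2 / b^2)` where `d` is geographical distance and `b` the
#' bandwidth, both in meters. The weight is 1 at zero distance and decays
#' strictly monotonically; at `d = b` it equals `exp(-1)`.
#'
#' @param d Distance(s) in meters, `>= 0`.
#' @param b Bandwidth in meters, `> 0`.
#' @return Weight(s) in `(0, 1]`.
#' @examples
#' gaussian_weight(0, 1000)     # 1
#' gaussian_weight(1000, 1000)  # exp(-1)
#' @export
gaussian_weight <- function(d, b) {
  check_number(b, "b", positive = TRUE)
  if (any(!is.finite(d)) || any(d < 0)) {
    abort_pm("distances must be finite and >= 0.", "value_error")
  }
  exp(-(d / b)^2)
}

# weights below this are treated as exactly zero so the effective
# neighbourhood of a local fit is bounded
WEIGHT_FLOOR <- 1e-12

#' Fit the global (nonspatial) linear calibration
#'
#' Ordinary least squares of regulatory PM2.5 on the collocated low-cost
#' reading(s): `E(Y | X) = beta0 + sum_b beta_b x_b`. One coefficient set
#' serves the whole network. Equals the kernel-weighted local fit in the
#' limit of all weights equal to 1.
#'
#' @param pairs Non-empty `collocated_pairs` with at least `B + 2` rows and a
#'   full-column-rank design.
#' @return An object of class `global_calibration`: fields `beta` (named
#'   vector, length `B + 1`), `n_train`, `B`, plus in-sample `fitted`,
#'   `r_squared` and `rmse`.
#' @export
fit_global <- function(pairs) {
  stopifnot(inherits(pairs, "collocated_pairs"))
  B <- attr(pairs, "B")
  if (nrow(pairs) < B + 2) {
    abort_pm(sprintf("need at least %d pairs to fit %d covariate(s).", B + 2, B),
             "empty_training_set_error")
  }
  X <- design_matrix(pairs)
  fit <- stats::lm.fit(X, pairs$y)
  if (fit$rank < ncol(X) || any(!is.finite(fit$coefficients))) {
    abort_pm("design matrix is rank deficient (e.g. constant covariate).",
             "singular_fit_error")
  }
  beta <- fit$coefficients
  fitted <- as.numeric(X %*% beta)
  res <- pairs$y - fitted
  structure(
    list(
      beta = beta,
      n_train = nrow(pairs),
      B = B,
      covariates = attr(pairs, "covariates"),
      fitted = fitted,
      r_squared = 1 - sum(res^2) / sum((pairs$y - mean(pairs$y))^2),
      rmse = sqrt(mean(res^2))
    ),
    class = "global_calibration"
  )
}

#' Fit the local calibration coefficients at one location
#'
#' Solves the kernel-weighted least-squares problem
#' `beta_hat(u, v) = (X' W X)^-1 X' W Y` with Gaussian weights
#' `W_jj = exp(-d_j^2 / b^2)`, `d_j` the distance from the target location to
#' training pair `j`'s anchor. The normal equations are solved in
#' weighted-centered form (covariates centered at their weighted means),
#' which makes the intercept exact and the slope block well scaled. If the
#' centered normal matrix is singular or has reciprocal condition number
#' below `1e-10`, a ridge `ridge_epsilon * trace-scale * I` is added and the
#' event is flagged.
#'
#' @param pairs Non-empty `collocated_pairs` (the training set).
#' @param u,v Target coordinate in meters.
#' @param bandwidth Gaussian kernel bandwidth in meters, `> 0`.
#' @param ridge_epsilon Relative ridge added to a near-singular centered
#'   normal matrix (default `1e-8`).
#' @return Named coefficient vector of length `B + 1`, with attribute
#'   `ridge` (`TRUE` if regularization was applied).
#' @export
fit_local <- function(pairs, u, v, bandwidth, ridge_epsilon = 1e-8) {
  stopifnot(inherits(pairs, "collocated_pairs"))
  check_number(u, "u"); check_number(v, "v")
  check_number(bandwidth, "bandwidth", positive = TRUE)
  B <- attr(pairs, "B")
  d <- sqrt((pairs$u - u)^2 + (pairs$v - v)^2)
  w <- gaussian_weight(d, bandwidth)
  w[w < WEIGHT_FLOOR] <- 0
  if (sum(w > 0) < B + 1) {
    abort_pm(sprintf(
      "only %d pair(s) carry non-negligible weight at (%.0f, %.0f) with bandwidth %g m; need %d.",
      sum(w > 0), u, v, bandwidth, B + 1), "underdetermined_local_fit_error")
  }
  Xs <- as.matrix(pairs[, paste0("x", seq_len(B)), drop = FALSE])
  y <- pairs$y
  sw <- sum(w)
  xbar <- colSums(w * Xs) / sw
  ybar <- sum(w * y) / sw
  Xc <- sweep(Xs, 2, xbar)
  A <- crossprod(Xc, w * Xc)
  rhs <- crossprod(Xc, w * (y - ybar))
  ridge <- FALSE
  rc <- tryCatch(rcond(A), error = function(e) 0)
  # reference scale from the uncentered weighted second moments: a centered
  # diagonal entry far below it means a locally constant covariate, which a
  # conditioning check alone cannot see when B = 1
  ref <- colSums(w * Xs^2)
  degenerate <- any(diag(A) <= 1e-10 * pmax(ref, .Machine$double.eps))
  if (!is.finite(rc) || rc < 1e-10 || degenerate) {
    scale <- sum(pmax(ref, diag(A))) / B
    if (!is.finite(scale) || scale <= 0) scale <- 1
    A <- A + diag(ridge_epsilon * scale, B)
    ridge <- TRUE
    pm_log(sprintf("near-singular local fit at (%.0f, %.0f); ridge applied", u, v),
           level = "debug")
  }
  slopes <- tryCatch(
    drop(solve(A, rhs)),
    error = function(e) abort_pm(
      paste0("local normal equations unsolvable: ", conditionMessage(e)),
      "underdetermined_local_fit_error")
  )
  beta <- c(ybar - sum(slopes * xbar), slopes)
  names(beta) <- c("(Intercept)", paste0("x", seq_len(B)))
  attr(beta, "ridge") <- ridge
  beta
}

#' Fit the spatially varying-coefficient calibration
#'
#' Runs [fit_local()] at every training anchor, producing one coefficient
#' set per collocated station: the local calibration
#' `E(Y | X, (u, v)) = beta0(u, v) + sum_b beta_b(u, v) x_b`. The training
#' pairs are retained so the model can be re-solved at any coordinate at
#' prediction time.
#'
#' @param pairs Non-empty `collocated_pairs`.
#' @param bandwidth Kernel bandwidth in meters; either a number or `"auto"`
#'   to select by leave-one-out cross-validation ([select_bandwidth()]).
#' @param ridge_epsilon Passed to [fit_local()].
#' @param candidates Candidate bandwidths when `bandwidth = "auto"`.
#' @return An object of class `spatial_calibration`: `bandwidth`,
#'   `local_coefficients` (tibble: `station_id`, `u`, `v`, `(Intercept)`,
#'   `x1`, ...), the training `pairs`, `ridge_epsilon`, `n_ridge` events, and
#'   in-sample `fitted`, `r_squared`, `rmse` at the anchors.
#' @export
fit_spatial <- function(pairs, bandwidth = "auto", ridge_epsilon = 1e-8,
                        candidates = NULL) {
  stopifnot(inherits(pairs, "collocated_pairs"))
  cv <- NULL
  if (identical(bandwidth, "auto")) {
    bandwidth <- select_bandwidth(pairs, candidates = candidates,
                                  ridge_epsilon = ridge_epsilon)
    cv <- attr(bandwidth, "cv")
  }
  check_number(bandwidth, "bandwidth", positive = TRUE)
  B <- attr(pairs, "B")
  betas <- purrr::map(seq_len(nrow(pairs)), function(i) {
    fit_local(pairs, pairs$u[i], pairs$v[i], bandwidth,
              ridge_epsilon = ridge_epsilon)
  })
  coef_mat <- do.call(rbind, betas)
  local_coefficients <- tibble::tibble(
    station_id = pairs$station_id,
    u = pairs$u,
    v = pairs$v
  )
  local_coefficients <- dplyr::bind_cols(
    local_coefficients, tibble::as_tibble(coef_mat))
  X <- design_matrix(pairs)
  fitted <- rowSums(X * coef_mat)
  res <- pairs$y - fitted
  structure(
    list(
      bandwidth = as.numeric(bandwidth),
      local_coefficients = local_coefficients,
      pairs = pairs,
      B = B,
      covariates = attr(pairs, "covariates"),
      ridge_epsilon = ridge_epsilon,
      n_ridge = sum(purrr::map_lgl(betas, ~ isTRUE(attr(.x, "ridge")))),
      bandwidth_cv = cv,
      fitted = fitted,
      r_squared = 1 - sum(res^2) / sum((pairs$y - mean(pairs$y))^2),
      rmse = sqrt(mean(res^2))
    ),
    class = "spatial_calibration"
  )
}

#' Default candidate bandwidth grid
#'
#' Eight log-spaced values from the 5th percentile of pairwise anchor
#' distances to the network diameter.
#' @param pairs `collocated_pairs`.
#' @param n Number of candidates.
#' @return Numeric vector of bandwidths (meters).
#' @export
bandwidth_grid <- function(pairs, n = 8) {
  stopifnot(inherits(pairs, "collocated_pairs"))
  d <- stats::dist(cbind(pairs$u, pairs$v))
  lo <- stats::quantile(d, 0.05, names = FALSE)
  hi <- max(d)
  if (lo <= 0) lo <- hi / 100
  exp(seq(log(lo), log(hi), length.out = n))
}

#' Select the kernel bandwidth by leave-one-out cross-validation
#'
#' For each candidate bandwidth, each training response `y_i` is predicted
#' by a local fit at its own anchor using the remaining `n - 1` pairs; the
#' candidate minimizing the root-mean-squared prediction error wins, with
#' ties broken toward the larger (smoother) bandwidth. A candidate for which
#' any held-out local fit is degenerate scores `Inf`.
#'
#' @param pairs Non-empty `collocated_pairs` with at least `B + 3` rows.
#' @param candidates Candidate bandwidths in meters (default:
#'   [bandwidth_grid()]).
#' @param ridge_epsilon Passed to [fit_local()].
#' @return The selected bandwidth (meters), with attribute `cv`: a tibble of
#'   `(bandwidth, cv_rmse)` for all candidates.
#' @export
select_bandwidth <- function(pairs, candidates = NULL, ridge_epsilon = 1e-8) {
  stopifnot(inherits(pairs, "collocated_pairs"))
  B <- attr(pairs, "B")
  if (nrow(pairs) < B + 3) {
    abort_pm("too few pairs for bandwidth cross-validation.",
             "empty_training_set_error")
  }
  if (is.null(candidates)) candidates <- bandwidth_grid(pairs)
  if (length(candidates) == 0 || any(candidates <= 0)) {
    abort_pm("candidates must be positive bandwidths.", "value_error")
  }
  scores <- purrr::map_dbl(candidates, function(b) {
    tryCatch(loo_rmse_spatial(pairs, b, ridge_epsilon), error = function(e) Inf)
  })
  if (all(!is.finite(scores))) {
    abort_pm("every candidate bandwidth yields degenerate local fits.",
             "bandwidth_selection_error")
  }
  best <- max(which(scores == min(scores)))  # tie -> larger bandwidth
  structure(candidates[best],
            cv = tibble::tibble(bandwidth = candidates, cv_rmse = scores))
}

loo_rmse_spatial <- function(pairs, bandwidth, ridge_epsilon = 1e-8) {
  n <- nrow(pairs)
  B <- attr(pairs, "B")
  X <- design_matrix(pairs)
  err <- purrr::map_dbl(seq_len(n), function(i) {
    train <- pairs[-i, , drop = FALSE]
    train <- new_collocated_pairs(train, attr(pairs, "max_distance"),
                                  attr(pairs, "n_excluded"), B,
                                  attr(pairs, "covariates"))
    beta <- fit_local(train, pairs$u[i], pairs$v[i], bandwidth,
                      ridge_epsilon = ridge_epsilon)
    pairs$y[i] - sum(X[i, ] * beta)
  })
  sqrt(mean(err^2))
}

loo_rmse_global <- function(pairs) {
  n <- nrow(pairs)
  X <- design_matrix(pairs)
  y <- pairs$y
  err <- purrr::map_dbl(seq_len(n), function(i) {
    fit <- stats::lm.fit(X[-i, , drop = FALSE], y[-i])
    y[i] - sum(X[i, ] * fit$coefficients)
  })
  sqrt(mean(err^2))
}

#' Leave-one-out cross-validated calibration RMSE
#'
#' Predicts each collocated station from the remaining pairs — by refitting
#' the global OLS (`model = "global"`) or the local weighted fit at the
#' held-out anchor (`model = "spatial"`) — and returns the RMSE of the
#' held-out predictions in µg/m³.
#'
#' @param pairs Non-empty `collocated_pairs`.
#' @param model `"global"` or `"spatial"`.
#' @param bandwidth Required for the spatial model (meters, or `"auto"`).
#' @param ridge_epsilon Passed to [fit_local()].
#' @return LOO-CV RMSE (µg/m³).
#' @export
cv_rmse <- function(pairs, model = c("global", "spatial"), bandwidth = NULL,
                    ridge_epsilon = 1e-8) {
  model <- match.arg(model)
  stopifnot(inherits(pairs, "collocated_pairs"))
  if (model == "global") {
    return(loo_rmse_global(pairs))
  }
  if (identical(bandwidth, "auto") || is.null(bandwidth)) {
    bandwidth <- select_bandwidth(pairs, ridge_epsilon = ridge_epsilon)
  }
  loo_rmse_spatial(pairs, as.numeric(bandwidth), ridge_epsilon)
}

#' Apply a fitted calibration to a sensor network
#'
#' Replaces every sensor's PM2.5 reading by its calibrated value. For a
#' global model this is the single affine map `beta0 + sum_b beta_b x_b`.
#' For a spatial model a fresh weighted least-squares fit is solved at each
#' sensor's own coordinate (true varying-coefficient prediction from the
#' stored training pairs); `method = "nearest_anchor"` instead reuses the
#' coefficients of the nearest training anchor, which is faster but
#' piecewise constant. Negative calibrated values are floored at 0 µg/m³
#' and counted (attribute `n_floored`).
#'
#' @param model A `global_calibration` or `spatial_calibration`.
#' @param sensors Non-empty [observation_set()] carrying every model
#'   covariate (`pm25` plus e.g. `rh` when the model was trained with it).
#' @param ... Method-specific arguments.
#' @return An [observation_set()] with calibrated `pm25`; attributes
#'   `n_floored` and (spatial) `n_ridge`.
#' @export
calibrate <- function(model, sensors, ...) {
  UseMethod("calibrate")
}

calibration_design <- function(model, sensors) {
  if (!inherits(sensors, "obs_set") || nrow(sensors) == 0) {
    abort_pm("`sensors` must be a non-empty observation set.", "empty_input_error")
  }
  covs <- model$covariates
  missing_cov <- setdiff(covs, names(sensors))
  if (length(missing_cov) > 0) {
    abort_pm(paste0("sensors lack model covariate(s): ",
                    paste(missing_cov, collapse = ", ")),
             "configuration_error")
  }
  X <- cbind(1, as.matrix(tibble::as_tibble(sensors)[, covs, drop = FALSE]))
  colnames(X) <- c("(Intercept)", paste0("x", seq_along(covs)))
  X
}

finish_calibrated <- function(sensors, values, extra_attrs = list()) {
  n_floored <- sum(values < 0)
  if (n_floored > 0) {
    pm_log(sprintf("floored %d negative calibrated value(s) at 0", n_floored))
    values <- pmax(values, 0)
  }
  out <- sensors
  out$pm25 <- values
  attr(out, "n_floored") <- n_floored
  for (nm in names(extra_attrs)) attr(out, nm) <- extra_attrs[[nm]]
  out
}

#' @rdname calibrate
#' @export
calibrate.global_calibration <- function(model, sensors, ...) {
  X <- calibration_design(model, sensors)
  finish_calibrated(sensors, as.numeric(X %*% model$beta))
}

#' @rdname calibrate
#' @param method `"local"` (re-solve the WLS at each sensor coordinate) or
#'   `"nearest_anchor"` (reuse the nearest training anchor's coefficients).
#' @export
calibrate.spatial_calibration <- function(model, sensors,
                                          method = c("local", "nearest_anchor"),
                                          ...) {
  method <- match.arg(method)
  X <- calibration_design(model, sensors)
  if (method == "local") {
    betas <- purrr::map(seq_len(nrow(sensors)), function(i) {
      fit_local(model$pairs, sensors$u[i], sensors$v[i], model$bandwidth,
                ridge_epsilon = model$ridge_epsilon)
    })
    coef_mat <- do.call(rbind, betas)
    n_ridge <- sum(purrr::map_lgl(betas, ~ isTRUE(attr(.x, "ridge"))))
  } else {
    lc <- model$local_coefficients
    idx <- purrr::map_int(seq_len(nrow(sensors)), function(i) {
      which.min((lc$u - sensors$u[i])^2 + (lc$v - sensors$v[i])^2)
    })
    coef_mat <- as.matrix(lc[idx, c("(Intercept)", paste0("x", seq_len(model$B)))])
    n_ridge <- 0L
  }
  finish_calibrated(sensors, rowSums(X * coef_mat),
                    extra_attrs = list(n_ridge = n_ridge))
}

#' Predict calibrated values for a covariate table
#'
#' @param object A fitted calibration.
#' @param newdata Tibble with columns `u`, `v` and the model covariates.
#' @param ... Unused.
#' @return Numeric vector of calibrated PM2.5 (not floored).
#' @export
predict.global_calibration <- function(object, newdata, ...) {
  X <- cbind(1, as.matrix(newdata[, object$covariates, drop = FALSE]))
  as.numeric(X %*% object$beta)
}

#' @rdname predict.global_calibration
#' @export
predict.spatial_calibration <- function(object, newdata, ...) {
  X <- cbind(1, as.matrix(newdata[, object$covariates, drop = FALSE]))
  betas <- purrr::map(seq_len(nrow(newdata)), function(i) {
    fit_local(object$pairs, newdata$u[i], newdata$v[i], object$bandwidth,
              ridge_epsilon = object$ridge_epsilon)
  })
  rowSums(X * do.call(rbind, betas))
}

#' @export
print.global_calibration <- function(x, ...) {
  cat("<global_calibration>\n")
  cat("  beta:", paste(sprintf("%s = %.4g", names(x$beta), x$beta),
                       collapse = ", "), "\n")
  cat(sprintf("  n_train = %d, in-sample R^2 = %.3f, RMSE = %.3f ug/m3\n",
              x$n_train, x$r_squared, x$rmse))
  invisible(x)
}

#' @export
print.spatial_calibration <- function(x, ...) {
  cat("<spatial_calibration>\n")
  cat(sprintf("  bandwidth = %.0f m, %d anchors, %d ridge event(s)\n",
              x$bandwidth, nrow(x$local_coefficients), x$n_ridge))
  cat(sprintf("  mean slope = %.3f, mean intercept = %.2f\n",
              mean(x$local_coefficients$x1),
              mean(x$local_coefficients$`(Intercept)`)))
  cat(sprintf("  in-sample R^2 = %.3f, RMSE = %.3f ug/m3 (at anchors)\n",
              x$r_squared, x$rmse))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a global calibration into one row per coefficient
#' @param x A `global_calibration`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`.
#' @method tidy global_calibration
#' @export
tidy.global_calibration <- function(x, ...) {
  tibble::tibble(term = names(x$beta), estimate = unname(x$beta))
}

#' Tidy a spatial calibration into one row per anchor per coefficient
#' @param x A `spatial_calibration`.
#' @param ... Unused.
#' @return Tibble with `station_id`, `u`, `v`, `term`, `estimate`.
#' @method tidy spatial_calibration
#' @export
tidy.spatial_calibration <- function(x, ...) {
  tidyr::pivot_longer(x$local_coefficients,
                      cols = -c("station_id", "u", "v"),
                      names_to = "term", values_to = "estimate")
}

#' @rdname tidy.global_calibration
#' @method glance global_calibration
#' @export
glance.global_calibration <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, rmse = x$rmse, n_train = x$n_train,
                 B = x$B)
}

#' @rdname tidy.spatial_calibration
#' @method glance spatial_calibration
#' @export
glance.spatial_calibration <- function(x, ...) {
  tibble::tibble(bandwidth = x$bandwidth, r_squared = x$r_squared,
                 rmse = x$rmse, n_train = nrow(x$local_coefficients),
                 B = x$B, n_ridge = x$n_ridge,
                 mean_slope = mean(x$local_coefficients$x1),
                 mean_intercept = mean(x$local_coefficients$`(Intercept)`))
}
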