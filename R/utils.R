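# Internal helpers: condition constructors and a leveled logger.

abort_pm <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "pmcalibrate_error"), ...)
}

#' @keywords internal
pm_log_level <- function() {
  lvl <- getOption("pmcalibrate.log_level", "info")
  match(lvl, c("debug", "info", "warn", "quiet"), nomatch = 2L)
}

pm_log <- function(..., level = "info") {
  if (match(level, c("debug", "info", "warn", "quiet")) >= pm_log_level()) {
    message("[pmcalibrate] ", ...)
  }
  invisible(NULL)
}

# mean earth radius, meters
EARTH_RADIUS_M <- 6371000

check_number <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1 || (finite && !is.finite(x))) {
    abort_pm(sprintf("`%s` must be a single finite number.", name), "value_error")
  }
  if (positive && x <= 0) {
    abort_pm(sprintf("`%s` must be > 0.", name), "value_error")
  }
  invisible(x)
}
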