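# Condition helpers. Every hard error raised by the package carries a class
# so callers (and the command-line wrapper) can map failures to exit codes:
# obsconf_usage_error, obsconf_data_error, obsconf_config_error.

stop_usage <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("obsconf_usage_error", "obsconf_error")))
}

stop_data <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("obsconf_data_error", "obsconf_error")))
}

stop_config <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("obsconf_config_error", "obsconf_error")))
}

#' Round half away from zero
#'
#' Percentages in reports are rounded half-up (2.35 -> 2.4), not to even as
#' [base::round()] does. Applied only when a report is formatted; internal
#' values stay unrounded.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
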