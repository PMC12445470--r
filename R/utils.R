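#' @importFrom rlang abort %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats lm coef dnorm optim qt rnorm sd
#' @importFrom utils read.csv write.csv
NULL

# classed aborts so callers can distinguish bad dimensions from bad values
stop_dimension <- function(msg) rlang::abort(msg, class = "schooldemand_error_dimension")
stop_validation <- function(msg) rlang::abort(msg, class = "schooldemand_error_validation")
stop_insufficient <- function(msg) rlang::abort(msg, class = "schooldemand_error_insufficient_data")
stop_coverage <- function(msg) rlang::abort(msg, class = "schooldemand_error_coverage")
stop_config <- function(msg) rlang::abort(msg, class = "schooldemand_error_config")
stop_range <- function(msg) rlang::abort(msg, class = "schooldemand_error_range")

#' Round half away from zero
#'
#' Reported percentage declines use commercial rounding (half away from zero),
#' not the round-half-even rule of [base::round()]: 0.05 rounds to 0.1 and
#' -0.05 to -0.1 at one decimal.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half away from zero to `digits` decimals.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# derive a per-stream 32-bit seed from a user seed; keeps streams decoupled
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 7919 + as.double(stream) * 104729) %% 2147483647)
}
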