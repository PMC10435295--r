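#' Round half away from zero
#'
#' Decimal rounding with the "half-up" convention used when rendering group
#' means to one decimal (base `round()` rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half-up to `digits` places.
#' @examples
#' round_half_up(2.25, 1) # 2.3
#' round_half_up(28 / 9, 1) # 3.1
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Format a mean to one decimal, half-up
#' @param x Numeric scalar.
#' @param digits Decimal places.
#' @return Character scalar, `"NA"` when `x` is missing.
#' @keywords internal
fmt1 <- function(x, digits = 1) {
  ifelse(is.na(x), "NA", sprintf(paste0("%.", digits, "f"), round_half_up(x, digits)))
}

abort_domain <- function(msg) {
  rlang::abort(msg, class = "svdscores_domain_error")
}

abort_validation <- function(msg, problems = NULL) {
  rlang::abort(msg, class = "svdscores_validation_error", problems = problems)
}

abort_missing_data <- function(msg) {
  rlang::abort(msg, class = "svdscores_missing_data_error")
}

abort_insufficient <- function(msg) {
  rlang::abort(msg, class = "svdscores_insufficient_data_error")
}

# scalar %||% is in rlang; re-export not needed internally
`%||%` <- rlang::`%||%`
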