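#' Round half away from zero
#'
#' Decimal rounding with the half-up tie rule used when matching tabulated
#' percentages (e.g. 2/13 = 15.38 reported as 15.4), as opposed to the
#' banker's rounding of [round()].
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(100 * 2 / 13, 1)
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# stop() wrapper with a subclassed condition so callers can test error types
abort_levo <- function(message, class) {
  abort(message, class = c(class, "levoCEA_error"))
}

is_probability <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x <= 1)
}

assert_probability <- function(x, what) {
  if (!is_probability(x)) {
    abort_levo(
      sprintf("`%s` must be a probability in [0, 1], got %s", what,
              paste(format(x), collapse = ", ")),
      "levoCEA_validation_error"
    )
  }
  invisible(x)
}
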