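#' Round half away from zero
#'
#' Presentation rounding for error rates. Unlike [base::round()], which
#' rounds half to even, ties go up: `round_half_up(4.725, 2)` is 4.73.
#' All published rates in the package's summaries use this rule.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 2).
#' @return `x` rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(100 * 5 / 358)  # 1.40
#' round_half_up(100 * 10 / 633) # 1.58
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  # sqrt(eps) guard keeps values that are exactly .5 after decimal expansion
  # from falling just below the tie because of binary representation
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

abort_modaudit <- function(message, class, ...) {
  abort(message, class = c(class, "modaudit_error"), ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
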