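#' Round half away from zero
#'
#' Deterministic rounding used for every reported percentage. Unlike
#' [base::round()] (banker's rounding), exact halves move away from zero, so
#' counts-to-percentage arithmetic reproduces conventionally rounded survey
#' tables.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 0).
#' @return Rounded numeric vector.
#' @examples
#' round_half_up(0.15, 1)  # 0.2
#' round(0.15, 1)          # 0.1 or 0.2 depending on binary representation
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * trunc(abs(x) * p + 0.5) / p
}

#' Percentage of a count, rounded
#'
#' @param n Numerator count(s).
#' @param total Denominator count.
#' @param digits Decimal places (default 1, the convention of stratified
#'   prevalence tables; combination tables use 2).
#' @return `100 * n / total` rounded half away from zero.
#' @examples
#' pct_of(20128, 114299)     # 17.6
#' pct_of(3595, 114299, 2)   # 3.15
#' @export
pct_of <- function(n, total, digits = 1) {
  round_half_up(100 * n / total, digits)
}
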