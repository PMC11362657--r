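# Money helpers. Costs are held to 2 decimal places (cents) so that
# aggregation and partition identities are exact: all sums are taken over
# integer cents, which doubles represent exactly far beyond any realistic
# fund size.

cents <- function(x) round(x * 100)

#' Round money to 2 decimal places
#' @param x numeric vector of currency amounts.
#' @return `x` rounded to the nearest cent, half away from zero.
#' @keywords internal
round_money <- function(x) {
  sign(x) * trunc(abs(x) * 100 + 0.5) / 100
}

# Exact sum of 2-dp money amounts.
sum_money <- function(x) sum(cents(x)) / 100

# Grouped exact sums of money; `by` is a factor-like vector.
rowsum_money <- function(x, by) {
  s <- rowsum(cents(x), by)
  s / 100
}

#' Round half away from zero
#'
#' Used for reported percentage shares: printed tables round halves away
#' from zero, whereas base [round()] rounds halves to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * trunc(abs(x) * p + 0.5) / p
}
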