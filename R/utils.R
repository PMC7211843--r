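# small shared helpers

#' Round half away from zero
#'
#' Display rounding for reports: exact halves move away from zero
#' (2.005 -> 2.01, -2.005 -> -2.01), matching how tabulated results are
#' conventionally printed, unlike [round()]'s round-half-even. Used only
#' for presentation -- computations always run at full precision.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @examples
#' round_half_away(c(0.125, -0.125), 2)
#' @export
round_half_away <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}
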