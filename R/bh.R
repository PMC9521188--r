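#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment: with sorted p-values p_(1) <=
#' ... <= p_(m), the adjusted value at rank i is
#' `min_(j >= i) min(1, p_(j) * m / j)`, reported in the input order.
#' `NA` entries are passed through and do not count toward m. A thin,
#' range-checked wrapper around `stats::p.adjust(method = "BH")`.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return Adjusted values, aligned to the input.
#' @examples
#' adjust_bh(c(0.005, 0.011, 0.02, 0.8))
#' @export
adjust_bh <- function(p) {
  assert_probability(p, "p")
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}
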