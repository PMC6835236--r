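#' Round half away from zero
#'
#' Fixed-precision rounding used for all reported percentages and densities.
#' Unlike [base::round()], which rounds half to even, ties are rounded away
#' from zero so that printed two-decimal summaries are reproducible across
#' platforms.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2).
#' @return Numeric vector rounded to `digits` decimals.
#' @export
#' @examples
#' round_half_up(2.125, 2)  # 2.13
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# stop() with a consistent prefix, no call
.err <- function(...) stop(..., call. = FALSE)

.assert_scalar_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x))
    .err(what, " must be a non-empty string")
  invisible(x)
}
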