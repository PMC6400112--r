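#' Round half away from zero
#'
#' Decimal rounding with ties going up (`0.5 -> 1`), the convention used for
#' all printed percentages and scanner counts in this package. Base R's
#' `round()` uses IEEE round-half-even, which disagrees on exact ties.
#'
#' @param x numeric vector.
#' @param digits integer; decimal places to keep.
#' @return `x` rounded to `digits` places, ties away from zero.
#' @examples
#' round_half_up(82.75, 1) # 82.8
#' round_half_up(218.333)  # 218
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# shared argument checks -----------------------------------------------------

stop_if_not_number <- function(x, name, lower = -Inf, upper = Inf,
                               strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single non-missing number", name),
         call. = FALSE)
  }
  if (strict_lower && x <= lower) {
    stop(sprintf("`%s` must be > %g (got %g)", name, lower, x), call. = FALSE)
  }
  if (!strict_lower && x < lower) {
    stop(sprintf("`%s` must be >= %g (got %g)", name, lower, x), call. = FALSE)
  }
  if (x > upper) {
    stop(sprintf("`%s` must be <= %g (got %g)", name, upper, x), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
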