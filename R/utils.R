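`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("afscreen_invalid_parameter", "error", "condition")))
}

stop_insufficient_beats <- function(msg) {
  stop(errorCondition(msg, class = c("afscreen_insufficient_beats", "error", "condition")))
}

stop_data_error <- function(msg) {
  stop(errorCondition(msg, class = c("afscreen_data_error", "error", "condition")))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid(sprintf("`%s` must be a single finite number", name))
  }
  if (x < lower || x > upper) {
    stop_invalid(sprintf("`%s` = %g outside [%g, %g]", name, x, lower, upper))
  }
  invisible(x)
}

#' Round half away from zero
#'
#' Decimal rounding with ties going up, matching the convention used when
#' percentages are reported to one decimal place (e.g. 95.45 -> 95.5). Base
#' `round()` rounds ties to even, which would print 0.25 as 0.2.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` places, ties away from zero.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

# Run `expr` under `seed` when supplied, otherwise in the current RNG stream.
with_seed_maybe <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

# Derive independent 31-bit sub-seeds from the active RNG stream.
draw_subseeds <- function(n) {
  sample.int(.Machine$integer.max, n, replace = FALSE)
}
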