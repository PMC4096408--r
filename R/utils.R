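#' Round half away from zero
#'
#' Reported percentages use commercial rounding (half away from zero) rather
#' than R's banker's rounding, so that e.g. `round_half_away(0.25, 1)` is 0.3.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_away(100 * 81 / 1419, 1)   # 5.7
#' round_half_away(100 * 1358 / 3438, 1) # 39.5
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# classed errors so callers/tests can distinguish failure modes
mlsa_stop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "mlsa_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# deterministic sub-seed stream: replicate r of root seed s is reproducible
# independently of execution order; kept below 2^31 - 1
sub_seed <- function(seed, r) {
  ((as.numeric(seed) %% 65011 + 1) * 32003 + r * 7) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a
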