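#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero
#' (so 0.25 -> 0.3 and -0.25 -> -0.3 at 1 dp), matching the convention used
#' in published registry tables. Base [round()] uses round-half-to-even and
#' would print, e.g., 0.2 for 0.25.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places (default 1).
#' @return numeric vector rounded half away from zero.
#' @examples
#' round_half_up(c(0.25, -0.25, 7.1737), 1)
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

logit <- function(p) log(p / (1 - p))

inv_logit <- function(x) 1 / (1 + exp(-x))

z_crit <- function(alpha) stats::qnorm(1 - alpha / 2)

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with a class so callers can distinguish configuration errors,
# row-level data errors and domain errors
gestage_error <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "gestage_error", "error")))
}
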