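#' Round half away from zero
#'
#' Fixed-precision rounding that carries halves upward (2.35 -> 2.4 at one
#' decimal), matching how the bundled benchmark tables are printed. Base
#' `round()` rounds halves to even, which differs on exactly-half values.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(2.35, -2.35), 1)
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Clamp scores to the [0, 100] scale used throughout the cognitive models.
# Returns the clamped vector with attribute "n_clamped"; emits a message when
# options(neurotrainr.verbose = TRUE) so clamping events are visible.
clamp_score <- function(x, lo = 0, hi = 100) {
  hit <- x < lo | x > hi
  out <- pmin(pmax(x, lo), hi)
  if (any(hit) && isTRUE(getOption("neurotrainr.verbose"))) {
    inform(sprintf("clamped %d score value(s) to [%g, %g]", sum(hit), lo, hi))
  }
  attr(out, "n_clamped") <- sum(hit)
  out
}

# Shared argument checks -----------------------------------------------------

check_number <- function(x, name, lower = -Inf, upper = Inf, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (finite && !is.finite(x)) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%g, %g]", name, lower, upper),
          class = "neurotrainr_config_error")
  }
  invisible(x)
}

config_error <- function(msg) abort(msg, class = "neurotrainr_config_error")
domain_error <- function(msg) abort(msg, class = "neurotrainr_domain_error")
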