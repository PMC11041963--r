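#' @keywords internal
"_PACKAGE"

# Internal assertion helpers. Errors are classed so callers (and the CLI)
# can distinguish validation failures from stage failures.

pt_stop <- function(msg, class = "pulsetherm_error", ...) {
  stop(structure(
    class = c(class, "pulsetherm_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

pt_validation_error <- function(msg) pt_stop(msg, class = "pulsetherm_validation_error")

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    pt_validation_error(sprintf("`%s` must be a single finite number", name))
  if (x < lower || x > upper)
    pt_validation_error(sprintf("`%s` = %g outside valid range [%g, %g]", name, x, lower, upper))
  invisible(x)
}

# Derive a stream-specific seed from a master seed so that independent
# random stages do not consume from one shared stream. Kept below 2^31.
derive_seed <- function(seed, stream) {
  m <- 2147483563
  as.integer((as.numeric(seed) %% m * 7919 + as.numeric(stream) * 104729) %% m)
}

#' Population standard deviation
#'
#' Standard deviation with the `n` denominator, used inside POS windows.
#' @param x numeric vector
#' @return scalar
#' @keywords internal
sd_pop <- function(x) {
  n <- length(x)
  if (n == 0L) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}
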