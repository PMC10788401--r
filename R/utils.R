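# Internal helpers shared across modules.

# Truncated-normal draw via inverse CDF (no rejection loop, so the RNG
# stream length does not depend on the draw's value).
rtruncnorm1 <- function(n, mean, sd, lower = -Inf) {
  if (sd == 0) return(rep(max(mean, lower), n))
  p_lo <- stats::pnorm(lower, mean, sd)
  u <- stats::runif(n, p_lo, 1)
  stats::qnorm(u, mean, sd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_recan <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_recan("'%s' must be a single finite number", name)
  if (positive && x <= 0)
    stop_recan("'%s' must be > 0", name)
  invisible(x)
}

# Binary labels to logical "is positive class" with validation.
as_positive <- function(labels, positive = "recanalized") {
  if (is.logical(labels)) return(labels)
  y <- labels == positive
  if (!any(y) && !is.factor(labels) && !is.character(labels) &&
      all(labels %in% c(0, 1))) {
    y <- labels == 1
  }
  y
}
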