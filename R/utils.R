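# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Integer copy-number calls use commercial rounding (2.5 -> 3, -2.5 -> -3)
#' rather than banker's rounding, so that the distance-to-integer rule is
#' symmetric around every half-integer.
#' @param x numeric vector.
#' @return numeric vector of rounded values.
#' @keywords internal
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

clamp01 <- function(x) pmin(1, pmax(0, x))

# Classed conditions: callers can distinguish format errors, validation
# errors and estimation failures programmatically (the CLI maps the class
# to its exit status).
ascn_stop <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "ascn_error")))
}

ascn_warn <- function(class, msg, ...) {
  warning(warningCondition(msg, ..., class = c(class, "ascn_warning")))
}

# Name of the sample a table refers to; tables without a sample column get
# a stable placeholder so sample-level outputs are always keyed.
sample_name <- function(tb) {
  if (!is.null(tb$sample) && length(tb$sample) > 0) as.character(tb$sample[1]) else "sample1"
}
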