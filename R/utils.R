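# Internal helpers shared across modules.

# Classed error conditions so callers can distinguish user/data/design errors
# programmatically (the CLI maps them to exit codes).
.err <- function(class, msg, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "iccpower_error")))
}

.check_number <- function(x, name, lower = -Inf, upper = Inf,
                          class = "iccpower_parameter_error") {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    .err(class, sprintf("`%s` must be a single finite number", name))
  }
  if (x < lower || x > upper) {
    .err(class, sprintf("`%s` = %g is outside [%g, %g]", name, x, lower, upper))
  }
  invisible(x)
}

# Derive a stream of child seeds from one master seed, each < 2^31.
.child_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

.log_msg <- function(level, ..., verbose = getOption("iccpower.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[", level, "] ", ...)
  invisible(NULL)
}
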