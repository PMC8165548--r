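# internal helpers shared across modules

# Run `code` under an explicit seed, restoring the caller's RNG state.
# seed = NULL means "use the ambient RNG stream" (still deterministic when the
# caller seeded it).
with_seed_ <- function(seed, code) {
  if (is.null(seed)) {
    force(code)
  } else {
    withr::with_seed(as.integer(seed), code)
  }
}

# Draw k child seeds from the current stream; keeps every stochastic routine
# reproducible from one master seed without sharing a stream across arms.
child_seeds <- function(k) {
  sample.int(.Machine$integer.max - 1L, k)
}

stop_param <- function(field, msg) {
  abort(sprintf("invalid `%s`: %s", field, msg), class = "svpower_param_error")
}

check_number <- function(x, field, lower = -Inf, upper = Inf,
                         allow_inf = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (!allow_inf && !is.finite(x))) {
    stop_param(field, "must be a single finite number")
  }
  if (x < lower) stop_param(field, sprintf("must be >= %s", lower))
  if (x > upper) stop_param(field, sprintf("must be <= %s", upper))
  invisible(x)
}

check_count <- function(x, field, lower = 1L) {
  check_number(x, field, lower = lower)
  if (x != as.integer(x)) stop_param(field, "must be a whole number")
  invisible(as.integer(x))
}

check_range <- function(x, field) {
  if (!is.numeric(x) || length(x) != 2L || any(!is.finite(x)) ||
      x[1] >= x[2]) {
    stop_param(field, "must be a length-2 numeric interval with lower < upper")
  }
  invisible(as.numeric(x))
}
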