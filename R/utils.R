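# Internal helpers: condition constructors, seeded RNG scoping, constants.

# Gas constant in kJ mol^-1 K^-1.
.RGAS <- 8.314462618e-3

abort_mhc2x <- function(message, class, ...) {
  stop(structure(
    class = c(class, "mhc2x_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

invalid_parameter <- function(message, ...) {
  abort_mhc2x(message, "mhc2x_invalid_parameter", ...)
}

fit_failure <- function(message, ...) {
  abort_mhc2x(message, "mhc2x_fit_failure", ...)
}

insufficient_data <- function(message, ...) {
  abort_mhc2x(message, "mhc2x_insufficient_data", ...)
}

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All generators route through this so
# no call touches global RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed != as.integer(seed)) {
    invalid_parameter("`seed` must be a single integer")
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit({
      assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
  } else {
    on.exit({
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

stopifnot_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    invalid_parameter(sprintf("`%s` must be finite and strictly positive", name))
  }
  invisible(x)
}

check_row_stochastic <- function(T, tol = 1e-12) {
  if (!is.matrix(T) || nrow(T) != ncol(T)) {
    invalid_parameter("transition matrix must be square")
  }
  if (any(T < -tol) || any(abs(rowSums(T) - 1) > max(tol, 1e-8))) {
    invalid_parameter("transition matrix must be row-stochastic with nonnegative entries")
  }
  invisible(T)
}
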