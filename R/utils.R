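# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG state
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so simulators are pure functions of their arguments and never
#' leak or consume global randomness.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Nearest-integer rounding with halves rounded up (away from zero for the
# positive quantities used here). Frame-index arithmetic must not depend on
# base round()'s round-half-to-even rule.
round_half_up <- function(x) {
  floor(x + 0.5)
}

# Stop with a classed condition so callers can catch specific failures.
stop_classed <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "twitchindex_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

check_number <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_classed("parameter_error", "`%s` must be a single number", name)
  }
  if (strict_min && x <= min) {
    stop_classed("parameter_error", "`%s` must be > %g", name, min)
  }
  if (!strict_min && x < min) {
    stop_classed("parameter_error", "`%s` must be >= %g", name, min)
  }
  if (x > max) {
    stop_classed("parameter_error", "`%s` must be <= %g", name, max)
  }
  invisible(x)
}

# Sample standard error of the mean; NA for n = 1 (undefined, not zero).
standard_error <- function(x) {
  n <- length(x)
  if (n < 2L) return(NA_real_)
  stats::sd(x) / sqrt(n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
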