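# Condition helpers. Three error classes map onto the CLI exit codes:
# validation/dimension -> 2, degenerate input -> 3.

stop_validation <- function(msg, class = "stcov_validation_error") {
  stop(structure(class = c(class, "stcov_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stop_dimension <- function(msg) {
  stop_validation(msg, class = c("stcov_dimension_error", "stcov_validation_error"))
}

stop_degenerate <- function(msg) {
  stop(structure(class = c("stcov_degenerate_error", "stcov_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

check_finite <- function(x, what) {
  if (!all(is.finite(x))) stop_validation(sprintf("%s contains non-finite values", what))
  invisible(x)
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` with the global random number generator seeded to `seed`
#' (Mersenne-Twister) and restores the caller's RNG state afterwards, so
#' seeded simulators never perturb user code.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop_validation("seed must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  expr
}

# scalar validators
check_count <- function(x, what, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min)
    stop_validation(sprintf("%s must be a single integer >= %d", what, min))
  as.integer(x)
}

check_positive_scalar <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_validation(sprintf("%s must be a single positive number", what))
  as.numeric(x)
}
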