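# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signal a validation error
#'
#' Validation failures carry the condition class `synieg_validation` so that
#' callers (and the command-line wrapper) can distinguish bad inputs
#' (exit code 2) from analysis infeasibility (exit code 3).
#' @noRd
abort_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("synieg_validation", "synieg_error")))
}

abort_infeasible <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("synieg_infeasible", "synieg_error")))
}

stopifnot_scalar_number <- function(x, name, min = -Inf, allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    abort_validation("`%s` must be a single number", name)
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_validation("`%s` must be a single finite number", name)
  if (x < min)
    abort_validation("`%s` must be >= %g (got %g)", name, min, x)
  invisible(NULL)
}

match_enum <- function(x, choices, name) {
  if (!is.character(x) || length(x) != 1L || !(x %in% choices))
    abort_validation("`%s` must be one of %s", name,
                     paste(sprintf('"%s"', choices), collapse = ", "))
  x
}

is_uniform_grid <- function(t, tol = 1e-8) {
  if (length(t) < 2L) return(TRUE)
  d <- diff(t)
  all(abs(d - d[1]) < tol * max(abs(d[1]), 1))
}
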