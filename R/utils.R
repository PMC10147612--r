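# internal helpers

abort_validation <- function(msg, ...) {
  stop(structure(
    class = c("ferrispec_validation_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

abort_solver <- function(msg, ...) {
  stop(structure(
    class = c("ferrispec_solver_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_number <- function(x, name, min = -Inf, max = Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_validation("'%s' must be a single finite number", name)
  lo_ok <- if (strict) x > min else x >= min
  hi_ok <- if (strict) x < max else x <= max
  if (!lo_ok || !hi_ok)
    abort_validation("'%s' = %g outside allowed range (%g, %g)", name, x, min, max)
  invisible(x)
}

# run code with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
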