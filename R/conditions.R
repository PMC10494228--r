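## Classed conditions so callers (and the CLI) can distinguish bad input from
## numerical failure.

stopInput <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("omegaCP_input_error", "omegaCP_error")))
}

stopNumerical <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("omegaCP_numerical_error", "omegaCP_error")))
}

## Run an expression with a seeded RNG without disturbing the caller's stream.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stopInput("'seed' must be a single finite number, got %s",
              paste(seed, collapse = ","))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
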