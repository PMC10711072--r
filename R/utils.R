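#' @keywords internal
"_PACKAGE"

# classed conditions so callers can distinguish degenerate geometry /
# degenerate statistics from programming errors
nq_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "nigraquant_error")))
}

nq_assert <- function(cond, msg, class = "nigraquant_invalid_input") {
  if (!isTRUE(cond)) nq_stop(msg, class)
}

# evaluate `expr` with a private RNG stream seeded by `seed`, restoring the
# caller's RNG state afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# stable sub-seed derivation so that each pipeline stage draws from its own
# stream; offsets keep the result a valid 32-bit integer
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647L)
}
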