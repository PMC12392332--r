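# Internal helpers: argument checks and RNG stream isolation.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  invisible(x)
}

# Each generator draws from its own stream derived from the master seed by a
# fixed offset, so adding a generator never perturbs another's output.  The
# multiplier keeps distinct (seed, offset) pairs distinct for the small seeds
# used in practice while staying inside 32-bit integer range.
stream_seed <- function(seed, offset) {
  s <- (abs(as.numeric(seed)) * 101 + offset) %% 2147483647
  as.integer(s)
}

# Evaluate `expr` under a private RNG state seeded with `seed`; the caller's
# .Random.seed is untouched.
with_stream <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}
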