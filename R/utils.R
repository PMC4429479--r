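# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_scalar <- function(x, name, lo = -Inf, hi = Inf, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  if (x < lo || x > hi)
    stopf("'%s' must be in [%s, %s], got %s", name, lo, hi, x)
  if (integerish && abs(x - round(x)) > 1e-8)
    stopf("'%s' must be a whole number", name)
  invisible(x)
}

# deterministic per-stage / per-chain seed derivation from one global seed;
# values stay below 2^31 so they are valid R integer seeds
derive_seeds <- function(seed, n, salt = 0L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((seed + 1000003L * salt) %% 2147483647L)
  sample.int(2147483646L, n)
}
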