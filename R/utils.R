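# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg) {
  stop(sprintf("invalid field '%s': %s", field, msg), call. = FALSE)
}

check_number <- function(x, field, lower = -Inf, upper = Inf,
                         integer = FALSE, strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_field(field, "must be a single finite number")
  if (integer && abs(x - round(x)) > 1e-8)
    stop_field(field, "must be an integer")
  if (strict_lower) {
    if (x <= lower) stop_field(field, sprintf("must be > %s", lower))
  } else if (x < lower) {
    stop_field(field, sprintf("must be >= %s", lower))
  }
  if (x > upper) stop_field(field, sprintf("must be <= %s", upper))
  if (integer) as.integer(round(x)) else x
}

# Deterministic sub-stream seed: adding later streams never perturbs earlier
# ones. Kept strictly below 2^31 (R integer range).
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(k)) %% 2147483647)
}

# Run code under a given seed without clobbering the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
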