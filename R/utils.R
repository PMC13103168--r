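# Internal utilities.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate code under a fixed RNG state, restoring the caller's stream after.
with_seed_ <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-item seed derivation from a master seed; stays within
# 32-bit integer range.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) + 7919 * as.double(i)) %% 2147483647)
}

abort_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_number <- function(x, field, lower = -Inf, upper = Inf,
                         integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_field(field, "must be a single finite number")
  if (x < lower || x > upper)
    abort_field(field, sprintf("must be in [%s, %s]", lower, upper))
  if (integerish && x != round(x))
    abort_field(field, "must be an integer")
  invisible(x)
}
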