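# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  }
  force(expr)
}

# Truncate toward zero at `digits` decimal places (how the reference
# percentages were printed; see stratified_rates()).
trunc_digits <- function(x, digits) {
  trunc(x * 10^digits) / 10^digits
}

# FNV-1a over a serialised object; stable provenance fingerprint without
# external dependencies.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2L))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
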