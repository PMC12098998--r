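# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Round half away from zero ("half-up" for the positive quantities used here).
# Points shown to participants are integers; R's round() uses banker's rounding
# which would send 62.5 to 62, not 63.
round_half_up <- function(x) {
  floor(x + 0.5)
}

# Derive child seeds from a master seed, reproducibly and independent of
# consumption order downstream.
spawn_seeds <- function(seed, n) {
  with_local_seed(seed, sample.int(2147483646L, n))
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
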