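# Internal helpers shared across modules.

# Round half away from zero (base round() is banker's rounding, which would
# make r = k*M/n depend on parity for exact halves).
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Convert a percent threshold to a cell count for a section of m cells.
pct_to_cells <- function(pct, m) {
  as.integer(round_half_away(pct * m / 100))
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards; seed = NULL leaves the global stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

is_count <- function(x, min = 0) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min &&
    abs(x - round(x)) < 1e-8
}

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

`%||%` <- function(a, b) if (is.null(a)) b else a
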