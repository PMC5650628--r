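# Internal helpers shared across modules.

# round half away from zero (R's round() is banker's rounding)
round_half_away <- function(x) {
  trunc(x + sign(x) * 0.5)
}

# atanh with |r| clamped away from 1 so perfect correlations stay finite
atanh_clamped <- function(r, eps = 1e-12) {
  atanh(pmin(pmax(r, -1 + eps), 1 - eps))
}

# correlation that is 0 (not NA) for zero-variance inputs
safe_cor <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0) {
    return(0)
  }
  cor(x, y)
}

# evaluate expr with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards; seed = NULL leaves the RNG stream untouched
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(expr)
}

# draw n independent sub-seeds (< 2^31) from the current RNG stream
draw_seeds <- function(n) {
  sample.int(.Machine$integer.max - 1L, n, replace = FALSE)
}

stop_ccabci <- function(...) {
  stop(..., call. = FALSE)
}
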