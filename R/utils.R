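# internal helpers shared across modules

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All stochastic operations in the
# package funnel through this so fixed seeds give bit-identical results
# without disturbing the user's RNG.
local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a child seed from a base seed and a stream index, kept within the
# 32-bit integer range R requires.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483629)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 1 && x == round(x)

is_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)

# population (n-denominator) standard deviation
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

# excess kurtosis, population moments
kurtosis_excess <- function(x) {
  x <- x - mean(x)
  m2 <- mean(x^2)
  if (m2 == 0) return(0)
  mean(x^4) / m2^2 - 3
}

rms <- function(x) sqrt(mean(x^2))
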