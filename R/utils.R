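# Internal helpers: seed handling and small numeric utilities.

# Evaluate `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards. Keeps every exported entry point
# reproducible without clobbering the user's session RNG.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic fan-out of one master seed into per-stage / per-unit seeds.
# Multipliers are small enough that the arithmetic stays exact in doubles
# and the result stays inside the 32-bit integer range.
derive_seed <- function(master, k) {
  master <- as.numeric(master) %% 2147483647
  k <- as.numeric(k)
  as.integer((master * 20011 + k * 7919 + 104729) %% 2147483647)
}

# Hash of a tag string to a numeric offset (for named stages).
tag_offset <- function(tag) {
  sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
}

stage_seed <- function(master, stage, k = 0L) {
  derive_seed(master, tag_offset(stage) + k)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x == round(x)
}

is_prob <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x <= 1
}

is_pos_num <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x > 0
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Linear-interpolated crossing time of y(t) through `level`, searching the
# segment [i, i+1]; t is the sample index grid.
cross_time <- function(y, i, level) {
  y0 <- y[i]; y1 <- y[i + 1L]
  if (y1 == y0) return(i)
  i + (level - y0) / (y1 - y0)
}

sample_skewness <- function(x) {
  n <- length(x)
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 <= 0) return(0)
  mean((x - m)^3) / s2^1.5
}

sample_kurtosis <- function(x) {
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 <= 0) return(0)
  mean((x - m)^4) / s2^2 - 3
}
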