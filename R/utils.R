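# Internal helpers: classed errors, scoped RNG, deterministic sub-stream seeds.

nl_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(paste0("nremlink_", class), "nremlink_error")))
}

nl_assert <- function(cond, msg, class = "invalid_argument") {
  if (!isTRUE(cond)) nl_stop(msg, class)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards so library code never perturbs user RNG streams.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-stream seed from a base seed and integer tags
# (mouse, day, modality index ...). Arithmetic stays below 2^53 so the
# computation is exact in doubles; the result is always a valid 32-bit seed.
derive_seed <- function(seed, ...) {
  h <- as.numeric(seed) %% 2147483647
  for (k in c(...)) {
    h <- (h * 69069 + as.numeric(k) + 1) %% 2147483647
  }
  as.integer(h)
}

# polynomial evaluation, coefficients in increasing degree order
polyval <- function(coeffs, x) {
  y <- numeric(length(x))
  for (i in seq_along(coeffs)) y <- y + coeffs[i] * x^(i - 1)
  y
}

logit <- function(p) log(p / (1 - p))

boxcar <- function(x, w) {
  if (w <= 1L) return(x)
  n <- length(x)
  k <- rep(1 / w, w)
  pad <- (w - 1L) %/% 2L
  xp <- c(rep(x[1], pad), x, rep(x[n], w - 1L - pad))
  as.numeric(stats::filter(xp, k, sides = 1))[w:(n + w - 1L)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
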