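## Internal numeric helpers. Curve evaluation must stay finite for
## arguments where mu_max * t can reach several hundred, so every
## exponential that can overflow is taken in log space.

## log(1 + exp(x)) without overflow (Maechler's cutoffs).
.log1pexp <- function(x) {
  out <- x
  lo <- x <= -37
  mid <- x > -37 & x <= 18
  hi <- x > 18 & x <= 33.3
  out[lo] <- exp(x[lo])
  out[mid] <- log1p(exp(x[mid]))
  out[hi] <- x[hi] + exp(-x[hi])
  ## x > 33.3: log1p(exp(x)) == x to double precision
  out
}

## log(exp(-a) + exp(-b) - exp(-a-b)) for a, b >= 0.
## The sum is strictly positive because exp(-a-b) <= min(exp(-a), exp(-b)).
.logSumBaranyi <- function(a, b) {
  m <- pmin(a, b)
  log(exp(-(a - m)) + exp(-(b - m)) - exp(-(a + b - m))) - m
}

## log(1 + exp(u) - exp(v)) with v <= u, used by the Baranyi response.
.log1pExpDiff <- function(u, v) {
  m <- pmax(u, 0)
  m + log(exp(-m) + exp(u - m) - exp(v - m))
}

.assertFiniteNumeric <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("invalid input: ", what, " must be finite numeric", call. = FALSE)
  invisible(x)
}

## Evaluate expr with the RNG seeded to `seed`, restoring the caller's
## RNG state afterwards so fitting never perturbs user simulations.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Deterministic sub-stream seed for channel `idx` of master seed.
.childSeed <- function(seed, idx) {
  s <- (as.double(seed) * 48271 + 104729 * as.double(idx)) %% 2147483646
  as.integer(s) + 1L
}

## letter labels a, b, ..., z, aa, ab, ... for homogeneous subsets
.letterLabels <- function(n) {
  if (n <= 26L) return(letters[seq_len(n)])
  extra <- as.vector(t(outer(letters, letters, paste0)))
  c(letters, extra)[seq_len(n)]
}
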