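# Internal numerical and plumbing helpers.

# log(sum(exp(x))) without overflow; -Inf-safe.
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b, guarded in log space.
logdiff <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

# Two-sided normal p, kept strictly inside (0, 1].
znorm_p <- function(z) {
  p <- 2 * pnorm(-abs(z))
  pmax(p, .Machine$double.xmin)
}

# Evaluate `expr` under `seed` when supplied, without disturbing the
# caller's RNG state.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) force(expr) else withr::with_seed(as.integer(seed), expr)
}

complement_allele <- function(a) chartr("ACGT", "TGCA", toupper(a))

is_palindromic <- function(ea, oa) complement_allele(ea) == toupper(oa)

`%||%` <- function(x, y) if (is.null(x)) y else x

stopifnot_scalar_num <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
}
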