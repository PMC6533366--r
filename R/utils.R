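# internal numeric helpers

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Gauss-Legendre nodes/weights on [a, b]
gl_rule <- function(n, a, b) {
  r <- pracma::gaussLegendre(n, a, b)
  list(nodes = r$x, weights = r$w)
}

# Gauss-Hermite rule for integrals against exp(-z^2)
gh_rule <- function(n) {
  if (n == 1L) return(list(nodes = 0, weights = sqrt(pi)))
  r <- pracma::gaussHermite(n)
  list(nodes = r$x, weights = r$w)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic per-subject seeds derived from a master seed (kept < 2^31)
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 1299721) %% 2147483563) + 1L
}
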